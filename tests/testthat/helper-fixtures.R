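# Shared fixture builders (everything is generated in code).

# small complete inbred panel plus lsmean phenotypes, aligned by line id
make_panel_data <- function(n_ind = 120, m_per = 40, n_qtl = 20,
                            h2 = 0.75, seed = 1, ...) {
  cfg <- sim_config(pop_type = "panel", n_ind = n_ind,
                    markers_per_chrom = m_per, n_qtl = n_qtl,
                    h2_target = h2, seed = seed, ...)
  g <- simulate_panel(cfg)
  sim <- simulate_phenotypes(g, cfg)
  ls <- ls_means(sim$records)
  stopifnot(identical(ls$genotype, line_ids(g)))
  list(cfg = cfg, geno = g, records = sim$records,
       arch = sim$architecture, y = ls$lsmean)
}

# hand-written HapMap text: 3 markers x 2 samples
write_hapmap_fixture <- function(path) {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "L1", "L2"), collapse = "\t")
  rows <- c(paste(c("m1", "A/C", "1", "100", "+", rep("NA", 6), "A", "C"),
                  collapse = "\t"),
            paste(c("m2", "G/T", "1", "200", "+", rep("NA", 6), "K", "G"),
                  collapse = "\t"),
            paste(c("m3", "A/G", "2", "50", "+", rep("NA", 6), "N", "R"),
                  collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2\tL3",
    "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "2\t500\tv2\tG\tT\t.\tPASS\t.\tGT\t1/1\t./.\t0/0"), path)
  path
}
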