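## Synthetic maize-population generator: diverse inbred panels, biparental
## doubled-haploid (DH) populations, dominant-marker collapse, missingness,
## and multi-environment phenotypes with a controlled additive architecture.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study conditions the package is built around: a
#' diverse tropical inbred panel (U-shaped allele-frequency spectrum with an
#' excess of rare alleles) or a biparental DH population on 10 chromosomes,
#' a purely additive trait at moderate-to-high heritability measured at the
#' genotype-mean level, and kernel-Zn-like trait scaling (baseline ~26
#' mg/kg, genetic SD ~3 mg/kg).
#'
#' @param pop_type `"panel"` (diverse inbreds, independent loci) or `"dh"`
#'   (doubled haploids from two inbred parents, linked loci).
#' @param n_ind Number of lines.
#' @param n_chrom Number of chromosomes (default 10, as in maize).
#' @param markers_per_chrom Markers per chromosome.
#' @param map_length_cM Genetic length per chromosome in centimorgans.
#' @param maf_spectrum Allele-frequency prior for panels: either a length-2
#'   vector of Beta shape parameters (default `c(0.3, 0.3)`, U-shaped so
#'   most markers are rare) or a single number giving one fixed frequency
#'   for all markers.
#' @param n_qtl Number of causal loci (sampled without replacement from the
#'   markers). `0` gives a null trait.
#' @param h2_target Narrow-sense heritability of the genotype lsmeans, in
#'   (0, 1\].
#' @param n_env Number of environments (locations).
#' @param n_rep Replicates per genotype x environment cell.
#' @param env_effect_sd SD of environment main effects (mg/kg).
#' @param genetic_sd SD of true breeding values on the trait scale (mg/kg).
#' @param baseline Overall trait mean (mg/kg).
#' @param ld_block_size Panel linkage-disequilibrium block size: 1 (default)
#'   simulates every locus independently; values > 1 group consecutive
#'   markers into blocks drawn from a small pool of founder haplotypes, so
#'   markers within a block are correlated (the block-haplotype mode used
#'   for marker-density experiments, where tagging through LD matters).
#' @param n_founder_haplotypes Founder-haplotype pool size per block in
#'   block mode; smaller pools give stronger LD.
#' @param missing_rate_target Default missing-call fraction for
#'   [inject_missing()], in \[0, 1).
#' @param seed Master integer seed; every generator derives its own
#'   substream from it (see [derive_seed()]).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(pop_type = c("panel", "dh"), n_ind = 236,
                       n_chrom = 10, markers_per_chrom = 100,
                       map_length_cM = 150, maf_spectrum = c(0.3, 0.3),
                       n_qtl = 40, h2_target = 0.75, n_env = 3, n_rep = 1,
                       env_effect_sd = 1.5, genetic_sd = 3.0, baseline = 26,
                       ld_block_size = 1, n_founder_haplotypes = 16,
                       missing_rate_target = 0.29, seed = 1) {
  pop_type <- match.arg(pop_type)
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
      stop(sprintf("invalid %s: must be an integer >= %d", nm, min))
  }
  chk_count(n_ind, "n_ind"); chk_count(n_chrom, "n_chrom")
  chk_count(markers_per_chrom, "markers_per_chrom")
  chk_count(n_env, "n_env"); chk_count(n_rep, "n_rep")
  chk_count(n_qtl, "n_qtl", min = 0)
  if (!is.finite(map_length_cM) || map_length_cM < 0)
    stop("invalid map_length_cM: must be >= 0")
  if (n_qtl > n_chrom * markers_per_chrom)
    stop("invalid n_qtl: exceeds total marker count")
  if (!is.finite(h2_target) || h2_target <= 0 || h2_target > 1)
    stop("invalid h2_target: must be in (0, 1]; for a null trait use n_qtl = 0")
  if (!is.finite(missing_rate_target) || missing_rate_target < 0 ||
      missing_rate_target >= 1)
    stop("invalid missing_rate_target: must be in [0, 1)")
  if (!(length(maf_spectrum) %in% c(1, 2)) || any(!is.finite(maf_spectrum)) ||
      any(maf_spectrum < 0))
    stop("invalid maf_spectrum: one fixed frequency or two Beta shapes")
  if (length(maf_spectrum) == 1 && maf_spectrum > 1)
    stop("invalid maf_spectrum: a fixed frequency must be in [0, 1]")
  if (env_effect_sd < 0 || genetic_sd < 0)
    stop("invalid env_effect_sd/genetic_sd: must be >= 0")
  chk_count(ld_block_size, "ld_block_size")
  chk_count(n_founder_haplotypes, "n_founder_haplotypes", min = 2)
  chk_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(
    pop_type = pop_type, n_ind = n_ind, n_chrom = n_chrom,
    markers_per_chrom = markers_per_chrom, map_length_cM = map_length_cM,
    maf_spectrum = maf_spectrum, n_qtl = n_qtl, h2_target = h2_target,
    n_env = n_env, n_rep = n_rep, env_effect_sd = env_effect_sd,
    genetic_sd = genetic_sd, baseline = baseline,
    ld_block_size = ld_block_size,
    n_founder_haplotypes = n_founder_haplotypes,
    missing_rate_target = missing_rate_target, seed = seed),
    class = "sim_config")
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic operation in the package draws its own seed substream
#' `derive_seed(master, index)` with a fixed index per operation, so that a
#' single master seed yields bit-identical end-to-end runs while keeping the
#' substreams of different operations (genotypes, phenotypes, missingness,
#' CV replicates, ...) decoupled. The scheme is a Lehmer step modulo
#' 2^31 - 1: `(master * 48271 + index) mod (2^31 - 1) + 1`.
#'
#' @param master Master integer seed.
#' @param index Non-negative substream index.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, index = 0) {
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m)
  as.integer((s * 48271 + as.numeric(index)) %% m + 1)
}

## substream indices for the generator family
SEED_GENO <- 0; SEED_PHENO <- 1; SEED_DOM <- 2; SEED_MISS <- 3

sim_map <- function(config) {
  m <- config$n_chrom * config$markers_per_chrom
  chrom <- rep(seq_len(config$n_chrom), each = config$markers_per_chrom)
  pos <- rep((seq_len(config$markers_per_chrom) - 0.5) /
               config$markers_per_chrom * config$map_length_cM,
             config$n_chrom)
  list(m = m, chrom = chrom, pos = pos)
}

#' Simulate a diverse inbred association panel
#'
#' Draws each marker's allele frequency from the configured spectrum (the
#' default Beta(0.3, 0.3) prior is U-shaped, so the majority of markers are
#' rare — the hallmark of diverse GBS panels), then samples every fully
#' homozygous line independently: dosage 2 with probability `p`, else 0.
#' Loci are independent; linkage disequilibrium is not modelled for panels.
#'
#' @param config A [sim_config()] with `pop_type = "panel"`.
#' @return A codominant [genotype_matrix()] with a nominal genetic map.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pop_type != "panel")
    stop("config$pop_type must be 'panel'")
  set.seed(derive_seed(config$seed, SEED_GENO))
  mp <- sim_map(config)
  p <- if (length(config$maf_spectrum) == 1) {
    rep(config$maf_spectrum, mp$m)
  } else {
    stats::rbeta(mp$m, config$maf_spectrum[1], config$maf_spectrum[2])
  }
  if (config$ld_block_size > 1) {
    ## block-haplotype mode: consecutive markers within a chromosome share a
    ## founder-haplotype pool, so each line's block is one doubled haplotype
    H <- config$n_founder_haplotypes
    d <- matrix(0, config$n_ind, mp$m)
    block <- (seq_len(mp$m) - 1) %/% config$ld_block_size
    block_id <- paste(mp$chrom, block)   # blocks never span chromosomes
    for (b in unique(block_id)) {
      idx <- which(block_id == b)
      founders <- vapply(p[idx], function(pj) stats::rbinom(H, 1, pj),
                         numeric(H))                      # H x |idx|
      pick <- sample.int(H, config$n_ind, replace = TRUE)
      d[, idx] <- 2 * founders[pick, , drop = FALSE]
    }
  } else {
    d <- vapply(p, function(pj) 2 * stats::rbinom(config$n_ind, 1, pj),
                numeric(config$n_ind))
  }
  dimnames(d) <- list(paste0("line", seq_len(config$n_ind)),
                      paste0("S", mp$chrom, "_", seq_len(mp$m)))
  genotype_matrix(d, "codominant", chrom = mp$chrom, pos = mp$pos)
}

#' Random inbred parent haplotypes for a DH cross
#'
#' Convenience generator of two fully homozygous parents on the config's
#' marker map: each parent's allele at each marker is Bernoulli(1/2), so
#' about half the markers segregate in the cross.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding the config's derived substream.
#' @return List with haplotype vectors `parent1`, `parent2` (0/1 alleles).
#' @export
sim_dh_parents <- function(config, seed = NULL) {
  set.seed(if (is.null(seed)) derive_seed(config$seed, SEED_GENO + 10)
           else seed)
  mp <- sim_map(config)
  list(parent1 = stats::rbinom(mp$m, 1, 0.5),
       parent2 = stats::rbinom(mp$m, 1, 0.5))
}

#' Simulate a doubled-haploid population from two inbred parents
#'
#' Each DH line is one doubled F1 gamete: per chromosome, the crossover
#' count is Poisson(`map_length_cM` / 100) with crossover positions uniform
#' on the map (Haldane model, no interference); the resulting recombinant
#' haplotype is doubled to a fully homozygous line. Markers segregate only
#' where the parents differ, and every DH allele is parental.
#'
#' @param config A [sim_config()] with `pop_type = "dh"`.
#' @param parent1,parent2 Parent haplotypes: 0/1 allele vectors over the
#'   config's marker map, or single-line codominant `geno_matrix` objects
#'   with map positions (dosage 1 anywhere is rejected as heterozygous).
#' @return A codominant [genotype_matrix()] of `n_ind` homozygous lines.
#' @export
simulate_dh <- function(config, parent1, parent2) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pop_type != "dh") stop("config$pop_type must be 'dh'")
  mp <- sim_map(config)
  h1 <- parent_haplotype(parent1, mp$m)
  h2 <- parent_haplotype(parent2, mp$m)
  set.seed(derive_seed(config$seed, SEED_GENO))
  n <- config$n_ind
  d <- matrix(0, n, mp$m)
  L <- config$map_length_cM
  for (i in seq_len(n)) {
    for (ch in seq_len(config$n_chrom)) {
      idx <- which(mp$chrom == ch)
      nco <- stats::rpois(1, L / 100)
      cuts <- sort(stats::runif(nco, 0, L))
      start <- sample(2L, 1)
      seg <- (start + findInterval(mp$pos[idx], cuts)) %% 2L  # 0 -> p2, 1 -> p1
      d[i, idx] <- 2 * ifelse(seg == 1L, h1[idx], h2[idx])
    }
  }
  dimnames(d) <- list(paste0("dh", seq_len(n)),
                      paste0("S", mp$chrom, "_", seq_len(mp$m)))
  genotype_matrix(d, "codominant", chrom = mp$chrom, pos = mp$pos)
}

parent_haplotype <- function(p, m) {
  if (inherits(p, "geno_matrix")) {
    if (nrow(p$dosages) != 1)
      stop("parent geno_matrix must contain exactly one line")
    d <- drop(p$dosages)
    if (anyNA(d)) stop("parent haplotype contains missing calls")
    if (any(d == 1)) stop("heterozygous parent rejected: DH parents must be ",
                          "fully homozygous")
    p <- d / 2
  }
  p <- as.numeric(p)
  if (length(p) != m)
    stop(sprintf("parent haplotype length %d != marker count %d",
                 length(p), m))
  if (!all(p %in% c(0, 1)))
    stop("heterozygous or invalid parent rejected: alleles must be 0/1")
  p
}

#' Collapse codominant markers to a dominant presence/absence platform
#'
#' Emulates tag-based dominant genotyping (rAmpSeq-style): per marker one
#' allele is designated "tag-present" (chosen at random under `seed`), and
#' any line carrying at least one copy of that allele scores 1, others 0.
#' On fully homozygous input the collapse is information-preserving per
#' marker up to allele labelling (see [expand_dominant()]); on heterozygous
#' input it merges dosages 1 and 2.
#'
#' Missing input calls are scored 0 by default (`missing_as_absent = TRUE`):
#' a presence/absence platform cannot distinguish a failed amplification
#' from true tag absence, which is the defining information loss of dominant
#' markers and the reason such data carry no missing-rate filter. Set
#' `missing_as_absent = FALSE` to keep the missing mask instead.
#'
#' @param geno A codominant [genotype_matrix()].
#' @param seed Seed for the per-marker tag-orientation draw.
#' @param missing_as_absent Score missing calls as 0 (tag dropout).
#' @return A dominant `geno_matrix` with the `present_allele` orientation
#'   recorded per marker.
#' @export
to_dominant <- function(geno, seed = NULL, missing_as_absent = TRUE) {
  if (geno$marker_class != "dominant") {
    d <- geno$dosages
  } else stop("input is already dominant")
  if (any(!is.na(d) & !d %in% c(0, 1, 2)))
    stop("dominant collapse requires integer dosages (raw calls)")
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(d)
  present <- sample(c("ref", "alt"), m, replace = TRUE)
  copies <- sweep(d, 2, ifelse(present == "alt", 0, 2), function(x, s)
    abs(x - s))
  pres <- (copies >= 1) * 1
  if (missing_as_absent) pres[is.na(pres)] <- 0
  dimnames(pres) <- dimnames(d)
  genotype_matrix(pres, "dominant", chrom = geno$chrom, pos = geno$pos,
                  present_allele = present)
}

#' Re-expand a dominant matrix derived from fully homozygous lines
#'
#' Inverse of [to_dominant()] valid only when the source lines were fully
#' homozygous ({0, 2} dosages) and no calls were dropped: presence maps back
#' to two copies of the tag allele, absence to zero, and the stored
#' `present_allele` orientation restores the original dosage coding.
#'
#' @param geno A dominant `geno_matrix` produced by [to_dominant()].
#' @return A codominant `geno_matrix`.
#' @export
expand_dominant <- function(geno) {
  if (geno$marker_class != "dominant") stop("input is not dominant")
  if (is.null(geno$present_allele))
    stop("no present_allele orientation recorded; cannot re-expand")
  copies <- 2 * geno$dosages
  d <- sweep(copies, 2, ifelse(geno$present_allele == "alt", 0, 2),
             function(x, s) abs(x - s))
  genotype_matrix(d, "codominant", chrom = geno$chrom, pos = geno$pos)
}

#' Simulate multi-environment phenotypes with additive architecture
#'
#' Samples `n_qtl` causal markers without replacement, draws their additive
#' effects from a zero-mean normal, and rescales them so the true breeding
#' values (centered QTL dosages times effects) have SD `genetic_sd` on the
#' trait scale. The per-record residual variance is then set analytically so
#' that the heritability of the genotype lsmeans equals `h2_target` in
#' expectation: `Var(residual of lsmean) = Var(TBV) (1 - h2) / h2`, scaled
#' up by `n_env * n_rep` for individual records. Environment main effects
#' are drawn once per environment and shared across genotypes, so
#' between-location correlations of genotype means are governed by `h2` and
#' the residual SD alone.
#'
#' @param geno A complete `geno_matrix` (run before [inject_missing()]).
#' @param config A [sim_config()].
#' @param qtl_indices Optional fixed causal-marker indices (length
#'   `config$n_qtl`), overriding the random draw — useful for building
#'   populations with controlled (e.g. disjoint) architectures.
#' @return List with `records` (long data frame: `genotype`, `environment`,
#'   `replicate`, `value`) and `architecture` (class `true_architecture`:
#'   `qtl_indices`, `qtl_markers`, `qtl_effects`, `true_breeding_values`).
#' @export
simulate_phenotypes <- function(geno, config, qtl_indices = NULL) {
  stopifnot(inherits(config, "sim_config"))
  d <- geno$dosages
  if (anyNA(d))
    stop("phenotype simulation needs complete genotypes; simulate before ",
         "inject_missing()")
  m <- ncol(d)
  if (config$n_qtl > m) stop("invalid n_qtl: exceeds marker count")
  set.seed(derive_seed(config$seed, SEED_PHENO))
  p <- allele_freqs(geno)
  W <- center_dosages(d, p, geno$marker_class)
  n <- nrow(d)
  if (!is.null(qtl_indices) && length(qtl_indices) != config$n_qtl)
    stop("qtl_indices length must equal config$n_qtl")
  if (config$n_qtl > 0) {
    qtl <- if (is.null(qtl_indices)) sort(sample.int(m, config$n_qtl))
           else sort(as.integer(qtl_indices))
    eff <- stats::rnorm(config$n_qtl)
    tbv <- drop(W[, qtl, drop = FALSE] %*% eff)
    s <- stats::sd(tbv)
    if (s > 0) {
      scale <- config$genetic_sd / s
      eff <- eff * scale
      tbv <- tbv * scale
    }
  } else {
    qtl <- integer(0)
    eff <- numeric(0)
    tbv <- rep(0, n)
  }
  names(tbv) <- rownames(d)
  v_tbv <- stats::var(tbv)
  if (v_tbv == 0) v_tbv <- config$genetic_sd^2  # null/monomorphic fallback
  ve_lsmean <- v_tbv * (1 - config$h2_target) / config$h2_target
  resid_sd <- sqrt(ve_lsmean * config$n_env * config$n_rep)
  env_eff <- stats::rnorm(config$n_env, 0, config$env_effect_sd)
  recs <- expand.grid(replicate = seq_len(config$n_rep),
                      genotype = rownames(d),
                      environment = paste0("env", seq_len(config$n_env)),
                      stringsAsFactors = FALSE)
  recs$value <- config$baseline +
    env_eff[match(recs$environment, paste0("env", seq_len(config$n_env)))] +
    tbv[recs$genotype] +
    stats::rnorm(nrow(recs), 0, resid_sd)
  recs <- recs[, c("genotype", "environment", "replicate", "value")]
  arch <- structure(
    list(qtl_indices = qtl, qtl_markers = colnames(d)[qtl],
         qtl_effects = eff, true_breeding_values = tbv),
    class = "true_architecture")
  list(records = recs, architecture = arch)
}

#' @export
print.true_architecture <- function(x, ...) {
  cat(sprintf("true_architecture: %d QTL, TBV sd = %.3f\n",
              length(x$qtl_indices), stats::sd(x$true_breeding_values)))
  invisible(x)
}

#' Mask genotype calls at random
#'
#' Sets calls to missing, emulating the pre-filter missingness of GBS data.
#' A scalar `rate` masks every cell independently with that probability; a
#' vector of length `ncol` gives each marker its own masking probability
#' (see [sim_missing_profile()] for a realistic dispersed profile — real
#' sequencing missingness varies enormously between markers, which is what
#' makes a per-marker missing-rate filter meaningful).
#'
#' @param geno A `geno_matrix`.
#' @param rate Missing probability per cell in \[0, 1): scalar or
#'   per-marker vector.
#' @param seed Optional integer seed.
#' @return A `geno_matrix` with missing calls.
#' @export
inject_missing <- function(geno, rate, seed = NULL) {
  m <- ncol(geno$dosages)
  if (!length(rate) %in% c(1, m))
    stop("rate must be a scalar or one value per marker")
  if (any(!is.finite(rate) | rate < 0 | rate >= 1))
    stop("rate must be in [0, 1)")
  if (all(rate == 0)) return(geno)
  if (!is.null(seed)) set.seed(seed)
  d <- geno$dosages
  n <- nrow(d)
  pm <- if (length(rate) == 1) rate else rep(rate, each = n)
  d[stats::runif(length(d)) < pm] <- NA
  out <- geno
  out$dosages <- d
  out
}

#' Dispersed per-marker missing-rate profile
#'
#' Draws one missing probability per marker from a Beta distribution with
#' the given mean and concentration (`shape1 = mean * conc`,
#' `shape2 = (1 - mean) * conc`). Low concentration gives the strongly
#' dispersed marker-level missingness typical of GBS before filtering:
#' many nearly complete markers alongside many mostly missing ones, with
#' the stated overall average. Values are truncated just below 1.
#'
#' @param m Number of markers.
#' @param mean Average missing rate (default 0.29, the GBS pre-filter
#'   regime this package emulates).
#' @param concentration Beta concentration; ~1.5 matches a wide U-shaped
#'   spread.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `m`, each in \[0, 1).
#' @export
sim_missing_profile <- function(m, mean = 0.29, concentration = 1.5,
                                seed = NULL) {
  if (mean < 0 || mean >= 1) stop("mean must be in [0, 1)")
  if (concentration <= 0) stop("concentration must be positive")
  if (!is.null(seed)) set.seed(seed)
  pmin(stats::rbeta(m, mean * concentration, (1 - mean) * concentration),
       1 - 1e-9)
}
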