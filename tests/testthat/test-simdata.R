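test_that("config validation names the offending field", {
  expect_error(sim_config(h2_target = 0), "h2_target")
  expect_error(sim_config(h2_target = 1.2), "h2_target")
  expect_error(sim_config(n_ind = 0), "n_ind")
  expect_error(sim_config(n_qtl = 1e6, markers_per_chrom = 10), "n_qtl")
  expect_error(sim_config(missing_rate_target = 1), "missing_rate_target")
  expect_error(sim_config(maf_spectrum = c(-1, 2)), "maf_spectrum")
})

test_that("panel simulation respects the allele-frequency prior", {
  # degenerate prior with all mass at frequency 0 gives an all-zero matrix
  cfg0 <- sim_config(pop_type = "panel", n_ind = 20, markers_per_chrom = 10,
                     maf_spectrum = 0, n_qtl = 0, seed = 2)
  expect_true(all(simulate_panel(cfg0)$dosages == 0))
  # same config and seed twice gives bitwise-identical output
  cfg <- sim_config(pop_type = "panel", n_ind = 50, markers_per_chrom = 20,
                    seed = 9)
  expect_identical(simulate_panel(cfg)$dosages, simulate_panel(cfg)$dosages)
  # all dosages homozygous
  expect_true(all(simulate_panel(cfg)$dosages %in% c(0, 2)))
})

test_that("rare-marker fraction matches the prior-predictive oracle", {
  cfg <- sim_config(pop_type = "panel", n_ind = 2000,
                    markers_per_chrom = 200, maf_spectrum = c(0.3, 0.3),
                    seed = 31)
  g <- simulate_panel(cfg)
  p_hat <- colMeans(g$dosages) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  frac <- mean(maf < 0.05)
  # Monte-Carlo prior-predictive: fresh Beta draws + binomial sampling
  set.seed(99)
  B <- 20000
  p0 <- rbeta(B, 0.3, 0.3)
  p_sim <- rbinom(B, 2000, p0) / 2000
  frac_oracle <- mean(pmin(p_sim, 1 - p_sim) < 0.05)
  se <- sqrt(frac_oracle * (1 - frac_oracle) * (1 / 2000 + 1 / B))
  expect_lt(abs(frac - frac_oracle), 2 * se)
})

test_that("block-haplotype mode creates within-block correlation only", {
  cfg <- sim_config(pop_type = "panel", n_ind = 400, markers_per_chrom = 20,
                    n_chrom = 2, ld_block_size = 5, maf_spectrum = c(2, 2),
                    n_founder_haplotypes = 4, seed = 77)
  g <- simulate_panel(cfg)
  d <- g$dosages
  poly <- which(apply(d, 2, sd) > 0)
  cm <- abs(cor(d[, poly]))
  block <- (poly - 1) %/% 5
  same <- outer(block, block, "==") & upper.tri(cm)
  diff_ <- (!outer(block, block, "==")) & upper.tri(cm)
  expect_gt(mean(cm[same]), 0.25)
  expect_lt(mean(cm[diff_]), 0.15)
  expect_true(all(d %in% c(0, 2)))
})

test_that("DH lines carry only parental alleles, doubled", {
  cfg <- sim_config(pop_type = "dh", n_ind = 60, markers_per_chrom = 25,
                    n_chrom = 4, seed = 12)
  p <- sim_dh_parents(cfg)
  g <- simulate_dh(cfg, p$parent1, p$parent2)
  expect_true(all(g$dosages %in% c(0, 2)))
  al <- g$dosages / 2
  ok <- sweep(al, 2, p$parent1, "==") | sweep(al, 2, p$parent2, "==")
  expect_true(all(ok))
  # identical parents give a fully monomorphic population
  g_mono <- simulate_dh(cfg, p$parent1, p$parent1)
  expect_true(all(apply(g_mono$dosages, 2, function(x) length(unique(x))) == 1))
  # heterozygous parent is rejected
  expect_error(simulate_dh(cfg, p$parent1, rep(0.5, 100)), "eterozygous")
  gm <- genotype_matrix(matrix(c(0, 1, rep(0, 98)), nrow = 1), "codominant")
  expect_error(simulate_dh(cfg, gm, p$parent2), "eterozygous")
})

test_that("zero map length transmits intact chromosomes at 1:1 ratio", {
  cfg <- sim_config(pop_type = "dh", n_ind = 300, markers_per_chrom = 30,
                    n_chrom = 1, map_length_cM = 0, n_qtl = 0, seed = 21)
  p1 <- rep(1, 30); p2 <- rep(0, 30)
  g <- simulate_dh(cfg, p1, p2)
  al <- g$dosages / 2
  from_p1 <- rowMeans(al)
  expect_true(all(from_p1 %in% c(0, 1)))   # chromosomes intact
  bt <- stats::binom.test(sum(from_p1), 300, 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("segregating DH allele frequencies concentrate at one half", {
  cfg <- sim_config(pop_type = "dh", n_ind = 1000, markers_per_chrom = 25,
                    n_chrom = 2, seed = 33)
  p <- sim_dh_parents(cfg)
  g <- simulate_dh(cfg, p$parent1, p$parent2)
  seg <- which(p$parent1 != p$parent2)
  freq <- colMeans(g$dosages[, seg, drop = FALSE]) / 2
  se3 <- 3 * sqrt(0.25 / 1000)
  expect_true(all(abs(freq - 0.5) < se3))
})

test_that("dominant collapse follows presence/absence semantics", {
  d <- cbind(m1 = c(0, 2, 2), m2 = c(2, 2, 2), m3 = c(0, 1, 2))
  g <- genotype_matrix(d, "codominant")
  gd <- to_dominant(g, seed = 5)
  expect_identical(gd$marker_class, "dominant")
  expect_true(all(gd$dosages %in% c(0, 1)))
  # carriers of the present allele score 1, non-carriers 0
  for (j in 1:3) {
    copies <- if (gd$present_allele[j] == "alt") d[, j] else 2 - d[, j]
    expect_equal(unname(gd$dosages[, j]), unname(as.numeric(copies >= 1)))
  }
  # monomorphic marker stays monomorphic
  expect_equal(length(unique(gd$dosages[, 2])), 1)
  expect_error(to_dominant(gd), "already dominant")
})

test_that("collapse on complete inbred data round-trips through expansion", {
  dat <- make_panel_data(n_ind = 40, m_per = 15, n_qtl = 5, seed = 14)
  gd <- to_dominant(dat$geno, seed = 6)
  back <- expand_dominant(gd)
  expect_equal(back$dosages, dat$geno$dosages)
})

test_that("dominant platforms score failed calls as tag absence", {
  g <- genotype_matrix(cbind(m1 = c(0, 2, NA)), "codominant")
  gd <- to_dominant(g, seed = 1)
  expect_false(anyNA(gd$dosages))
  gd2 <- to_dominant(g, seed = 1, missing_as_absent = FALSE)
  expect_true(is.na(gd2$dosages[3, 1]))
})

test_that("noise-free and null trait architectures behave as limits", {
  cfg1 <- sim_config(pop_type = "panel", n_ind = 80, markers_per_chrom = 30,
                     n_qtl = 10, h2_target = 1, seed = 51)
  g <- simulate_panel(cfg1)
  sim <- simulate_phenotypes(g, cfg1)
  ls <- ls_means(sim$records)
  expect_equal(cor(ls$lsmean,
                   sim$architecture$true_breeding_values[ls$genotype]), 1,
               tolerance = 1e-12)
  # null architecture: equal breeding values, ~zero location correlation
  cfg0 <- sim_config(pop_type = "panel", n_ind = 200, markers_per_chrom = 30,
                     n_qtl = 0, h2_target = 0.5, seed = 52)
  g0 <- simulate_panel(cfg0)
  sim0 <- simulate_phenotypes(g0, cfg0)
  expect_equal(var(sim0$architecture$true_breeding_values), 0)
  lc <- location_correlations(sim0$records)
  expect_true(all(abs(lc$r) < 0.2))
  # true breeding values are the centered QTL dosages times effects
  cfg2 <- sim_config(pop_type = "panel", n_ind = 60, markers_per_chrom = 30,
                     n_qtl = 8, seed = 53)
  g2 <- simulate_panel(cfg2)
  sim2 <- simulate_phenotypes(g2, cfg2)
  W <- sweep(g2$dosages, 2, colMeans(g2$dosages), "-")
  tbv <- drop(W[, sim2$architecture$qtl_indices] %*%
                sim2$architecture$qtl_effects)
  expect_equal(unname(sim2$architecture$true_breeding_values), unname(tbv),
               tolerance = 1e-12)
})

test_that("realized lsmean heritability is calibrated to its target", {
  h2r <- sapply(1:50, function(s) {
    cfg <- sim_config(pop_type = "panel", n_ind = 300,
                      markers_per_chrom = 50, n_qtl = 40, h2_target = 0.75,
                      n_env = 3, seed = 500 + s)
    g <- simulate_panel(cfg)
    sim <- simulate_phenotypes(g, cfg)
    ls <- ls_means(sim$records)
    var(sim$architecture$true_breeding_values) / var(ls$lsmean)
  })
  expect_lt(abs(mean(h2r) - 0.75), 0.05)
})

test_that("realized heritability tracks targets with unit slope", {
  targets <- c(0.2, 0.5, 0.8)
  means <- sapply(targets, function(t) {
    mean(sapply(1:50, function(s) {
      cfg <- sim_config(pop_type = "panel", n_ind = 500,
                        markers_per_chrom = 30, n_qtl = 30, h2_target = t,
                        seed = 700 + s)
      g <- simulate_panel(cfg)
      sim <- simulate_phenotypes(g, cfg)
      ls <- ls_means(sim$records)
      var(sim$architecture$true_breeding_values) / var(ls$lsmean)
    }))
  })
  slope <- coef(lm(means ~ targets))[2]
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)
})

test_that("missing injection hits its rate and composes with QC", {
  dat <- make_panel_data(n_ind = 100, m_per = 20, n_qtl = 5, seed = 61)
  g <- dat$geno
  expect_identical(inject_missing(g, 0, seed = 1)$dosages, g$dosages)
  big <- sim_config(pop_type = "panel", n_ind = 1000,
                    markers_per_chrom = 100, seed = 62)
  gb <- inject_missing(simulate_panel(big), 0.29, seed = 63)
  frac <- mean(is.na(gb$dosages))
  se3 <- 3 * sqrt(0.29 * 0.71 / 1e6)
  expect_lt(abs(frac - 0.29), se3)
  expect_error(inject_missing(g, 1), "rate")
  # masked cells are excluded from MAF downstream
  gm <- inject_missing(g, 0.3, seed = 64)
  qc <- compute_qc(gm)
  j <- which(qc$missing_rate > 0 & qc$maf_defined)[1]
  col <- gm$dosages[, j]
  expect_equal(qc$maf[j],
               min(mean(col, na.rm = TRUE) / 2, 1 - mean(col, na.rm = TRUE) / 2))
  # per-marker profile: overall average near the profile mean
  prof <- sim_missing_profile(2000, mean = 0.29, seed = 65)
  gp <- inject_missing(simulate_panel(sim_config(pop_type = "panel",
    n_ind = 500, markers_per_chrom = 200, seed = 66)), prof, seed = 67)
  expect_lt(abs(mean(is.na(gp$dosages)) - mean(prof)), 0.02)
  # and marker-level rates are genuinely dispersed
  qcp <- compute_qc(gp)
  expect_gt(mean(qcp$missing_rate < 0.2), 0.2)
  expect_gt(mean(qcp$missing_rate > 0.5), 0.1)
})

test_that("all generators are bitwise reproducible under a fixed seed", {
  cfg <- sim_config(pop_type = "panel", n_ind = 40, markers_per_chrom = 15,
                    n_qtl = 6, seed = 71)
  g1 <- simulate_panel(cfg); g2 <- simulate_panel(cfg)
  expect_identical(g1$dosages, g2$dosages)
  s1 <- simulate_phenotypes(g1, cfg); s2 <- simulate_phenotypes(g2, cfg)
  expect_identical(s1$records$value, s2$records$value)
  expect_identical(s1$architecture$qtl_effects, s2$architecture$qtl_effects)
  expect_identical(inject_missing(g1, 0.2, seed = 5)$dosages,
                   inject_missing(g1, 0.2, seed = 5)$dosages)
  expect_identical(to_dominant(g1, seed = 3)$dosages,
                   to_dominant(g1, seed = 3)$dosages)
  cfgd <- sim_config(pop_type = "dh", n_ind = 30, markers_per_chrom = 15,
                     seed = 72)
  p <- sim_dh_parents(cfgd)
  expect_identical(simulate_dh(cfgd, p$parent1, p$parent2)$dosages,
                   simulate_dh(cfgd, p$parent1, p$parent2)$dosages)
})
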