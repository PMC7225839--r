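## Evaluation battery: replicated k-fold cross-validation and the design
## sweeps around it (training-set size, marker density, marker quality,
## phenotype-stratified training sets, cross-population transfer, MAS).

new_cv_result <- function(accuracies, meta = list()) {
  acc <- as.numeric(accuracies)
  ok <- acc[!is.na(acc)]
  structure(list(
    accuracies = acc,
    mean = if (length(ok)) mean(ok) else NA_real_,
    sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
    se = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else NA_real_,
    meta = meta), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  lbl <- paste(names(x$meta), vapply(x$meta, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = " ")
  cat(sprintf("cv_result: %d replicate(s), mean accuracy %.3f (sd %.3f, se %.3f)\n",
              length(x$accuracies), x$mean, x$sd, x$se))
  if (nzchar(lbl)) cat("  ", lbl, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  data.frame(n_reps = length(object$accuracies), mean = object$mean,
             sd = object$sd, se = object$se,
             min = suppressWarnings(min(object$accuracies, na.rm = TRUE)),
             max = suppressWarnings(max(object$accuracies, na.rm = TRUE)))
}

#' Random k-fold partition of n lines
#'
#' Assigns each of `n` lines to one of `k` near-equal folds uniformly at
#' random (fold sizes differ by at most one). Every CV replicate in the
#' package draws its partition from this function.
#'
#' @param n Number of lines.
#' @param k Number of folds.
#' @return Integer vector of fold labels in `1:k`, length `n`.
#' @export
make_folds <- function(n, k) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  sample(rep(seq_len(k), length.out = n))
}

## one CV replicate: partition into k folds, train on k-1, return the mean
## of the per-fold accuracies (the replicate accuracy)
cv_replicate <- function(y, geno, ref, k, fold_seed) {
  n <- length(y)
  set.seed(fold_seed)
  folds <- make_folds(n, k)
  accs <- vapply(seq_len(k), function(f) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- rrblup(y[train], subset_lines(geno, train))
    pred <- predict(fit, subset_lines(geno, test))
    accuracy(pred, ref[test])
  }, numeric(1))
  mean(accs)
}

#' Replicated k-fold cross-validation of genomic prediction accuracy
#'
#' The study's workhorse: per replicate, lines are partitioned into `k`
#' near-equal disjoint folds; each fold's GEBVs are predicted from a model
#' trained (with its own REML ridge estimate and training-frequency
#' centering) on the remaining folds, and the replicate accuracy is the mean
#' of the per-fold Pearson correlations against the reference. Defaults
#' follow the fivefold scheme.
#'
#' @param y Phenotype vector used to train (typically genotype lsmeans).
#' @param geno A complete [genotype_matrix()] with rows matching `y`.
#' @param k Number of folds (default 5).
#' @param n_reps Number of replicated partitions.
#' @param seed Master seed; replicate `i` uses `derive_seed(seed, i)`.
#' @param ref Reference values for accuracy; defaults to `y` (on simulated
#'   data pass the true breeding values instead).
#' @return A `cv_result`: replicate accuracies plus mean/sd/se and metadata.
#' @export
kfold_cv <- function(y, geno, k = 5, n_reps = 150, seed = 1, ref = y) {
  n <- length(y)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  if (floor(n / k) < 3)
    stop("fold size below 3: accuracy undefined; lower k")
  if (length(ref) != n) stop("ref must have one value per line")
  acc <- vapply(seq_len(n_reps), function(i)
    cv_replicate(y, geno, ref, k, derive_seed(seed, i)), numeric(1))
  new_cv_result(acc, list(k = k, n_reps = n_reps, seed = seed,
                          n = n, m = ncol(geno$dosages)))
}

#' Training-population-size sweep
#'
#' For each training fraction, repeatedly draws a random training subset of
#' that fraction of lines, fits the model on it, and measures accuracy on
#' the complement. Cells whose training set would fall below 10 lines (or
#' whose validation set below 3) are flagged and not run.
#'
#' @param y,geno,seed,ref As in [kfold_cv()].
#' @param fractions Training fractions in (0, 1); default 10--90% by 10%.
#' @param n_reps Replicates per fraction.
#' @return Named list of `cv_result`, one per fraction; flagged cells carry
#'   `meta$flag`.
#' @export
tps_sweep <- function(y, geno, fractions = seq(0.1, 0.9, by = 0.1),
                      n_reps = 100, seed = 1, ref = y) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly in (0, 1)")
  n <- length(y)
  out <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_train <- round(f * n)
    meta <- list(fraction = f, n_train = n_train, n_reps = n_reps, seed = seed)
    if (n_train < 10 || n - n_train < 3) {
      meta$flag <- "training_or_validation_too_small"
      out[[as.character(f)]] <- new_cv_result(rep(NA_real_, n_reps), meta)
      next
    }
    acc <- vapply(seq_len(n_reps), function(i) {
      set.seed(derive_seed(seed, fi * 100000 + i))
      train <- sample.int(n, n_train)
      valid <- setdiff(seq_len(n), train)
      fit <- rrblup(y[train], subset_lines(geno, train))
      accuracy(predict(fit, subset_lines(geno, valid)), ref[valid])
    }, numeric(1))
    out[[as.character(f)]] <- new_cv_result(acc, meta)
  }
  out
}

#' Marker-density sweep
#'
#' For each marker count, every replicate draws a fresh uniform marker
#' subset of that size and runs one full k-fold CV replicate on it. Counts
#' exceeding the available markers are skipped, with the skip recorded in
#' the result metadata.
#'
#' @param y,geno,k,seed,ref As in [kfold_cv()].
#' @param marker_counts Marker subset sizes to test.
#' @param n_reps Replicates per count.
#' @return Named list of `cv_result`, one per (run) marker count; skipped
#'   counts appear with `meta$flag = "skipped_count_exceeds_markers"`.
#' @export
density_sweep <- function(y, geno, marker_counts, n_reps = 100, k = 5,
                          seed = 1, ref = y) {
  m <- ncol(geno$dosages)
  out <- list()
  for (si in seq_along(marker_counts)) {
    s <- marker_counts[si]
    meta <- list(n_markers = s, n_reps = n_reps, k = k, seed = seed)
    if (s > m) {
      warning(sprintf("marker count %d exceeds available %d markers; skipped",
                      s, m))
      meta$flag <- "skipped_count_exceeds_markers"
      out[[as.character(s)]] <- new_cv_result(numeric(0), meta)
      next
    }
    acc <- vapply(seq_len(n_reps), function(i) {
      sub <- subsample_markers(geno, s, seed = derive_seed(seed, si * 100000 + i))
      cv_replicate(y, sub, ref, k, derive_seed(seed, si * 100000 + i + 50000))
    }, numeric(1))
    out[[as.character(s)]] <- new_cv_result(acc, meta)
  }
  out
}

#' Marker-quality grid (MAF x missing-rate filtering)
#'
#' Reproduces the structure of a marker-quality experiment: for every
#' combination of MAF threshold (strict `>`) and missing-rate level
#' (inclusive `<=`, so a 0% level means "no missing calls"), the raw
#' genotypes are filtered, mean-imputed and run through replicated k-fold
#' CV. For dominant platforms pass `missing_levels = NULL` to grid over MAF
#' only (dominant calls carry no missing distinction).
#'
#' @param geno_raw Unfiltered `geno_matrix`, typically with missing calls.
#' @param y,k,seed,ref As in [kfold_cv()].
#' @param maf_levels MAF thresholds.
#' @param missing_levels Missing-rate levels, or `NULL` for MAF-only cells.
#' @param n_reps CV replicates per cell.
#' @return Data frame with one row per cell: `maf_gt`, `missing_le`,
#'   `n_markers`, `mean`, `sd`, `se`, `flag`; the full `cv_result` objects
#'   are in `attr(, "results")`.
#' @export
quality_grid <- function(geno_raw, y, maf_levels = seq(0.1, 0.4, by = 0.1),
                         missing_levels = seq(0, 0.8, by = 0.2),
                         n_reps = 150, k = 5, seed = 1, ref = y) {
  qc <- compute_qc(geno_raw)
  miss_grid <- if (is.null(missing_levels)) NA_real_ else missing_levels
  rows <- list(); results <- list(); cell <- 0
  for (ml in miss_grid) {
    for (maf in maf_levels) {
      cell <- cell + 1
      keep <- qc$maf_defined & qc$maf > maf
      if (!is.na(ml)) keep <- keep & qc$missing_rate <= ml
      keep[is.na(keep)] <- FALSE
      n_mark <- sum(keep)
      if (n_mark == 0) {
        rows[[cell]] <- data.frame(maf_gt = maf, missing_le = ml,
                                   n_markers = 0, mean = NA_real_,
                                   sd = NA_real_, se = NA_real_,
                                   flag = "empty_marker_set")
        results[[cell]] <- NULL
        next
      }
      sub <- impute_mean(subset_markers(geno_raw, which(keep)))
      res <- kfold_cv(y, sub, k = k, n_reps = n_reps,
                      seed = derive_seed(seed, cell), ref = ref)
      rows[[cell]] <- data.frame(maf_gt = maf, missing_le = ml,
                                 n_markers = n_mark, mean = res$mean,
                                 sd = res$sd, se = res$se, flag = "")
      results[[cell]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Phenotype-stratified training-set scenarios
#'
#' Builds the training set by rank of the phenotype (lsmean) and validates
#' on the *whole* population, training lines included — deliberate fidelity
#' to the published design (set `strict_holdout = TRUE` to validate on the
#' complement instead). Scenarios: `random` (uniform draw, replicated),
#' `top` / `bottom` (highest / lowest fraction), `middle` (central fraction
#' symmetric about the median), `two_tails` (half the training set from
#' each extreme; the extra line of an odd-size set goes to the top tail).
#' The rank-based scenarios are deterministic, so they run once.
#'
#' @param y,geno,seed,ref As in [kfold_cv()].
#' @param scenario One of `"random"`, `"top"`, `"bottom"`, `"middle"`,
#'   `"two_tails"`.
#' @param fraction Training fraction in (0, 1\].
#' @param n_reps Replicates (only the `random` scenario re-randomizes).
#' @param strict_holdout Validate on the complement rather than everyone.
#' @return A `cv_result`.
#' @export
scenario_training <- function(y, geno, scenario = c("random", "top", "bottom",
                                                    "middle", "two_tails"),
                              fraction = 0.5, n_reps = 10, seed = 1, ref = y,
                              strict_holdout = FALSE) {
  scenario <- match.arg(scenario)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(y)
  n_train <- max(1L, round(fraction * n))
  meta <- list(scenario = scenario, fraction = fraction, n_train = n_train,
               seed = seed)
  if (n_train < 10) {
    meta$flag <- "training_too_small"
    return(new_cv_result(NA_real_, meta))
  }
  ord <- order(y, decreasing = TRUE)   # rank 1 = largest lsmean
  pick <- switch(scenario,
    top = ord[seq_len(n_train)],
    bottom = rev(ord)[seq_len(n_train)],
    middle = {
      inc <- order(y)
      start <- floor((n - n_train) / 2) + 1
      inc[start:(start + n_train - 1)]
    },
    two_tails = {
      n_top <- ceiling(n_train / 2)
      c(ord[seq_len(n_top)], rev(ord)[seq_len(n_train - n_top)])
    },
    random = NULL)
  run_one <- function(train) {
    valid <- if (strict_holdout) setdiff(seq_len(n), train) else seq_len(n)
    fit <- rrblup(y[train], subset_lines(geno, train))
    accuracy(predict(fit, subset_lines(geno, valid)), ref[valid])
  }
  if (scenario == "random") {
    acc <- vapply(seq_len(n_reps), function(i) {
      set.seed(derive_seed(seed, i))
      run_one(sample.int(n, n_train))
    }, numeric(1))
  } else {
    acc <- run_one(pick)
    meta$deterministic <- TRUE
  }
  new_cv_result(acc, meta)
}

#' Cross-population genomic prediction
#'
#' Trains one model on the full training population and predicts the full
#' validation population, after intersecting the two marker panels by id.
#' Validation dosages are centered with the training population's allele
#' frequencies (the transfer contract).
#'
#' @param y_train,geno_train Training phenotypes and complete genotypes.
#' @param y_valid,geno_valid Validation reference values and genotypes.
#' @param min_shared Minimum number of shared markers required.
#' @return List with `r` (transfer accuracy), `n_shared_markers`,
#'   `n_train`, `n_valid`, and the fitted `rrblup` model.
#' @export
cross_population <- function(y_train, geno_train, y_valid, geno_valid,
                             min_shared = 50) {
  shared <- intersect(marker_ids(geno_train), marker_ids(geno_valid))
  if (length(shared) < min_shared)
    stop(sprintf("only %d shared markers (need >= %d)",
                 length(shared), min_shared))
  gt <- subset_markers(geno_train, match(shared, marker_ids(geno_train)))
  gv <- subset_markers(geno_valid, match(shared, marker_ids(geno_valid)))
  fit <- rrblup(y_train, gt)
  pred <- predict(fit, gv)
  list(r = accuracy(pred, y_valid), n_shared_markers = length(shared),
       n_train = length(y_train), n_valid = length(y_valid), fit = fit)
}

#' Marker-assisted-selection style prediction on a named marker subset
#'
#' Runs the identical replicated k-fold CV machinery restricted to a named
#' list of markers — the few-marker MAS analogue of whole-genome prediction
#' (e.g. a panel of validated trait-associated SNPs).
#'
#' @param y,geno,k,n_reps,seed,ref As in [kfold_cv()].
#' @param marker_subset Character vector of marker ids (must all exist).
#' @return A `cv_result`.
#' @export
mas_prediction <- function(y, geno, marker_subset, k = 5, n_reps = 150,
                           seed = 1, ref = y) {
  unknown <- setdiff(marker_subset, marker_ids(geno))
  if (length(unknown))
    stop("unknown marker id(s): ", paste(utils::head(unknown, 10),
                                         collapse = ", "))
  sub <- subset_markers(geno, match(marker_subset, marker_ids(geno)))
  res <- kfold_cv(y, sub, k = k, n_reps = n_reps, seed = seed, ref = ref)
  res$meta$markers <- marker_subset
  res
}

#' Welch t-test between two sets of replicate accuracies
#'
#' @param res_a,res_b `cv_result` objects (or bare accuracy vectors) with at
#'   least two replicates each.
#' @return Data frame with `mean_diff` (a minus b), `t`, `df`, `p`, and a
#'   `flag` column noting degenerate inputs.
#' @export
compare_accuracies <- function(res_a, res_b) {
  a <- if (inherits(res_a, "cv_result")) res_a$accuracies else as.numeric(res_a)
  b <- if (inherits(res_b, "cv_result")) res_b$accuracies else as.numeric(res_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two replicates on each side")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(data.frame(mean_diff = mean(a) - mean(b), t = NA_real_,
                      df = NA_real_, p = NA_real_,
                      flag = "degenerate_variance"))
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(mean_diff = mean(a) - mean(b),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, flag = "")
}
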