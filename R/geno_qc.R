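#' Per-marker quality-control statistics
#'
#' Computes, over non-missing calls only, each marker's minor-allele
#' frequency and missing rate. For codominant markers the allele frequency is
#' `p = sum(dosage) / (2 * n_called)` and MAF is `min(p, 1 - p)`; for
#' dominant markers the presence-class frequency `q` (fraction of called
#' lines carrying the tag) takes the place of `p`. Markers with no calls at
#' all get `missing_rate = 1` and `NA` MAF (flagged in `maf_defined`).
#'
#' @param geno A [genotype_matrix()].
#' @return A data frame with columns `marker_id`, `maf`, `missing_rate`,
#'   `maf_defined`.
#' @export
compute_qc <- function(geno) {
  d <- geno$dosages
  n <- nrow(d)
  n_called <- colSums(!is.na(d))
  missing_rate <- 1 - n_called / n
  sums <- colSums(d, na.rm = TRUE)
  p <- if (geno$marker_class == "codominant") {
    sums / (2 * n_called)
  } else {
    sums / n_called
  }
  p[n_called == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  data.frame(marker_id = colnames(d), maf = maf,
             missing_rate = missing_rate, maf_defined = !is.na(maf),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on MAF and missing rate
#'
#' Retains markers whose MAF is strictly greater than `maf_gt` and (when
#' `missing_lt` is given) whose missing rate is strictly below `missing_lt`,
#' mirroring the usual "MAF greater than 0.05 and missing rate less than 20%"
#' SNP-panel rule. Markers with undefined MAF (no calls) are always dropped.
#' Marker order is preserved.
#'
#' @param geno A `geno_matrix`.
#' @param qc Output of [compute_qc()] for `geno`; recomputed when `NULL`.
#' @param maf_gt MAF threshold (strict `>`), in \[0, 0.5\].
#' @param missing_lt Missing-rate threshold (strict `<`) in (0, 1\], or
#'   `NULL` to skip the missing filter (the dominant-platform regime).
#' @param inclusive_missing Use `<=` instead of `<` for the missing filter;
#'   needed to express a "0% missing" level (see [quality_grid()]).
#' @return Filtered `geno_matrix`.
#' @export
filter_markers <- function(geno, qc = NULL, maf_gt = 0.05, missing_lt = NULL,
                           inclusive_missing = FALSE) {
  if (is.null(qc)) qc <- compute_qc(geno)
  if (maf_gt < 0 || maf_gt > 0.5) stop("maf_gt must be in [0, 0.5]")
  keep <- qc$maf_defined & qc$maf > maf_gt
  if (!is.null(missing_lt)) {
    if (missing_lt < 0 || missing_lt > 1) stop("missing_lt must be in [0, 1]")
    keep <- keep & if (inclusive_missing) qc$missing_rate <= missing_lt
                   else qc$missing_rate < missing_lt
  }
  keep[is.na(keep)] <- FALSE
  subset_markers(geno, which(keep))
}

#' Mean-impute missing genotype calls
#'
#' Replaces every missing call by its marker's non-missing mean dosage (so
#' imputed values are fractional). The marker mean is unchanged by
#' construction. Markers with no calls at all cannot be imputed.
#'
#' @param geno A `geno_matrix`.
#' @return A complete (no-missing) `geno_matrix`.
#' @export
impute_mean <- function(geno) {
  d <- geno$dosages
  na <- is.na(d)
  if (!any(na)) return(geno)
  all_missing <- colSums(!na) == 0
  if (any(all_missing))
    stop("markers with all calls missing cannot be mean-imputed; ",
         "filter first: ", paste(colnames(d)[all_missing][1:min(5, sum(all_missing))],
                                 collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(na, arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- geno
  out$dosages <- d
  out
}

#' Random marker subsample
#'
#' Draws `n_markers` markers uniformly without replacement, keeping genomic
#' (input) order in the result. Deterministic under `seed`.
#'
#' @param geno A `geno_matrix`.
#' @param n_markers Subset size.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `geno_matrix` with `n_markers` markers.
#' @export
subsample_markers <- function(geno, n_markers, seed = NULL) {
  m <- ncol(geno$dosages)
  if (n_markers > m)
    stop(sprintf("n_markers (%d) exceeds available markers (%d)",
                 n_markers, m))
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(m, n_markers))
  subset_markers(geno, keep)
}
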