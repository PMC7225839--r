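#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes the realized additive relationship matrix from a complete
#' (imputed) genotype matrix. Codominant dosages are centered by twice the
#' observed allele frequency and the cross-product is normalized by
#' `c = sum(2 p (1 - p))`; dominant presence/absence markers are centered by
#' the observed presence frequency with `c = sum(p (1 - p))`. The result has
#' average diagonal near 1 and is symmetric positive semi-definite up to
#' numerical tolerance.
#'
#' @param geno A complete [genotype_matrix()] (mean-impute first if needed).
#' @return An object of class `grm`: list with `mat` (n x n matrix, line ids
#'   as dimnames), `c_norm` (the normalization constant, also the
#'   marker-ridge/GRM variance-scale conversion factor), `freqs` (per-marker
#'   allele or presence frequencies), and `marker_class`.
#' @export
grm <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop("genotype matrix contains missing calls; impute first")
  if (ncol(d) == 0) stop("no markers")
  p <- allele_freqs(geno)
  W <- center_dosages(d, p, geno$marker_class)
  c_norm <- grm_norm_const(p, geno$marker_class)
  if (c_norm <= 0)
    stop("all markers are monomorphic: GRM normalization constant is zero")
  K <- tcrossprod(W) / c_norm
  dimnames(K) <- list(rownames(d), rownames(d))
  structure(list(mat = K, c_norm = c_norm, freqs = p,
                 marker_class = geno$marker_class),
            class = "grm")
}

allele_freqs <- function(geno) {
  if (geno$marker_class == "codominant") colMeans(geno$dosages) / 2
  else colMeans(geno$dosages)
}

center_dosages <- function(d, p, marker_class) {
  ctr <- if (marker_class == "codominant") 2 * p else p
  sweep(d, 2, ctr, "-")
}

grm_norm_const <- function(p, marker_class) {
  if (marker_class == "codominant") sum(2 * p * (1 - p))
  else sum(p * (1 - p))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d (%s markers), mean diagonal %.3f, c = %.3f\n",
              nrow(x$mat), ncol(x$mat), x$marker_class,
              mean(diag(x$mat)), x$c_norm))
  invisible(x)
}

#' Export a GRM as CSV
#' @param K A `grm` object.
#' @param path Output path; line ids become the header and first column.
#' @return `path`, invisibly.
#' @export
write_grm <- function(K, path) {
  df <- data.frame(line_id = rownames(K$mat), K$mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
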