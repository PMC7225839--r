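#' Fit a ridge-regression BLUP genomic prediction model
#'
#' The package's central fitting function. Fits the marker mixed model
#' `y = 1 mu + Z u + e` with `u ~ N(0, I sigma_u^2)` and
#' `e ~ N(0, I sigma_e^2)` — ridge-regression BLUP, the dual of GBLUP with a
#' VanRaden relationship matrix. When `lambda` is not supplied, the ridge
#' parameter is estimated by REML on the matched GRM (see [reml()]) and
#' converted to the marker scale through the GRM normalization constant:
#' `lambda = c * V_e / sigma_K` (with `sigma_K` the additive-variance
#' coefficient on the GRM scale), which makes the marker-ridge and GRM
#' parameterizations agree exactly. The intercept is the generalized
#' least-squares mean, and marker effects solve the ridge normal equations
#' `(Z'Z + lambda I) u = Z'(y - mu)`, computed through the equivalent n x n
#' system so that cost scales with line number, not marker number.
#'
#' @param y Numeric phenotype vector (one value per line; typically lsmeans).
#' @param geno Either a complete [genotype_matrix()] (dosages are centered
#'   internally by the training allele frequencies, which are stored for
#'   prediction) or an already-centered numeric matrix `Z` (n x m). With a
#'   bare matrix the GRM normalization uses the mean column sum of squares.
#' @param lambda Optional fixed ridge parameter (marker scale); estimated by
#'   REML when `NULL`.
#' @return An object of class `rrblup` with components `mu`, `u` (named
#'   marker effects), `lambda`, `varcomp` (a `varcomp` or `NULL` when
#'   `lambda` was fixed), `freqs`, `marker_class`, `K` (the training GRM),
#'   `c_norm`, `fitted`, `residuals`, `y`.
#' @examples
#' cfg <- sim_config(pop_type = "panel", n_ind = 60, markers_per_chrom = 30,
#'                   n_qtl = 10, h2_target = 0.8, seed = 1)
#' g <- simulate_panel(cfg)
#' sim <- simulate_phenotypes(g, cfg)
#' ls <- ls_means(sim$records)
#' fit <- rrblup(ls$lsmean, g)
#' fit
#' @export
rrblup <- function(y, geno, lambda = NULL) {
  if (any(!is.finite(y))) stop("y must be finite")
  n <- length(y)
  if (inherits(geno, "geno_matrix")) {
    if (anyNA(geno$dosages))
      stop("genotype matrix contains missing calls; impute_mean() first")
    if (nrow(geno$dosages) != n)
      stop("length(y) must equal the number of lines")
    p <- allele_freqs(geno)
    Z <- center_dosages(geno$dosages, p, geno$marker_class)
    c_norm <- grm_norm_const(p, geno$marker_class)
    marker_class <- geno$marker_class
  } else {
    Z <- as.matrix(geno)
    if (nrow(Z) != n) stop("length(y) must equal nrow(Z)")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("m", seq_len(ncol(Z)))
    p <- NULL
    c_norm <- sum(colMeans(Z^2))
    marker_class <- NA_character_
  }
  m <- ncol(Z)
  if (m == 0) stop("no markers to fit")
  if (c_norm <= 0) stop("all markers are monomorphic")
  K <- tcrossprod(Z) / c_norm
  vc <- NULL
  if (is.null(lambda)) {
    vc <- reml(y, K)
    lambda <- c_norm * vc$lambda
  } else if (lambda <= 0) stop("lambda must be positive")
  ## n x n dual system: V0 = Z Z' + lambda I
  V0 <- tcrossprod(Z)
  diag(V0) <- diag(V0) + lambda
  ch <- chol(V0)
  ones <- rep(1, n)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), ones))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  u <- drop(crossprod(Z, Vi_r))
  names(u) <- colnames(Z)
  fitted <- mu + drop(Z %*% u)
  structure(
    list(mu = mu, u = u, lambda = lambda, varcomp = vc, freqs = p,
         marker_class = marker_class, marker_ids = colnames(Z), K = K,
         c_norm = c_norm, fitted = fitted, residuals = y - fitted, y = y,
         line_ids = rownames(Z)),
    class = "rrblup")
}

#' Predict genomic estimated breeding values
#'
#' Computes `GEBV = mu + Z_new u` for new lines. When the model was fitted
#' from a `geno_matrix`, `newdata` must be a `geno_matrix` of the same marker
#' class containing every training marker (matched by id and reordered);
#' its dosages are centered with the *training* allele frequencies, as the
#' prediction contract requires. A bare numeric matrix is taken as already
#' centered on the training frequencies.
#'
#' @param object An `rrblup` fit.
#' @param newdata New genotypes (`geno_matrix` or centered matrix). Defaults
#'   to the training fitted values when omitted.
#' @param ... Unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.rrblup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "geno_matrix")) {
    if (is.null(object$freqs))
      stop("model was fitted on a pre-centered matrix; supply a centered ",
           "matrix, not a geno_matrix")
    if (anyNA(newdata$dosages))
      stop("new genotype matrix contains missing calls; impute_mean() first")
    if (!identical(newdata$marker_class, object$marker_class))
      stop("marker class of new data (", newdata$marker_class,
           ") differs from training (", object$marker_class, ")")
    missing <- setdiff(object$marker_ids, marker_ids(newdata))
    if (length(missing))
      stop("new data lacks training markers: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)",
                                             length(missing) - 10) else "")
    d <- newdata$dosages[, object$marker_ids, drop = FALSE]
    Z <- center_dosages(d, object$freqs, object$marker_class)
  } else {
    Z <- as.matrix(newdata)
    if (ncol(Z) != length(object$u))
      stop("new matrix has ", ncol(Z), " markers; model has ",
           length(object$u))
  }
  gebv <- object$mu + drop(Z %*% object$u)
  names(gebv) <- rownames(Z)
  gebv
}

#' @export
coef.rrblup <- function(object, ...) object$u

#' @export
fitted.rrblup <- function(object, ...) object$fitted

#' @export
residuals.rrblup <- function(object, ...) object$residuals

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("rrblup fit: %d lines, %d markers (lambda = %.4g)\n",
              length(x$y), length(x$u), x$lambda))
  if (!is.null(x$varcomp))
    cat(sprintf("  REML: V_A = %.4f, V_e = %.4f, h2 = %.3f\n",
                x$varcomp$V_A, x$varcomp$V_e, x$varcomp$h2))
  cat(sprintf("  intercept (GLS mean) = %.4f\n", x$mu))
  invisible(x)
}

#' @export
summary.rrblup <- function(object, ...) {
  out <- list(n = length(object$y), m = length(object$u),
              lambda = object$lambda, mu = object$mu,
              varcomp = object$varcomp,
              fit_cor = stats::cor(object$fitted, object$y),
              top_effects = utils::head(
                object$u[order(abs(object$u), decreasing = TRUE)], 5))
  class(out) <- "summary.rrblup"
  out
}

#' @export
print.summary.rrblup <- function(x, ...) {
  cat(sprintf("rrblup: n = %d, m = %d, lambda = %.4g, mu = %.4f\n",
              x$n, x$m, x$lambda, x$mu))
  if (!is.null(x$varcomp)) print(x$varcomp)
  cat(sprintf("  cor(fitted, observed) = %.3f\n", x$fit_cor))
  cat("  largest |marker effects|:\n")
  print(round(x$top_effects, 5))
  invisible(x)
}

#' @export
plot.rrblup <- function(x, ...) {
  graphics::plot(x$y, x$fitted, xlab = "observed phenotype",
                 ylab = "fitted GEBV",
                 main = "RR-BLUP fitted genetic values", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate phenotype vectors from a fitted model
#'
#' Draws `y* = mu + g + e` with `g ~ N(0, K V_A)` and `e ~ N(0, I V_e)` using
#' the REML variance components and the training GRM. Only available when
#' the ridge parameter was REML-estimated.
#'
#' @param object An `rrblup` fit with a `varcomp` component.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame, one column per simulation.
#' @export
simulate.rrblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$varcomp))
    stop("simulate() needs REML variance components (fit with lambda = NULL)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  K <- object$K * object$varcomp$V_A
  diag(K) <- diag(K) + 1e-8 * max(diag(K), 1)
  L <- chol(K)
  out <- replicate(nsim, object$mu + drop(crossprod(L, stats::rnorm(n))) +
                     stats::rnorm(n, sd = sqrt(object$varcomp$V_e)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Prediction accuracy (Pearson correlation)
#'
#' The field's accuracy statistic: the Pearson correlation between predicted
#' and reference values (phenotype lsmeans on real data, simulated breeding
#' values in validation studies). Undefined when either side has zero
#' variance or fewer than three pairs; returns `NA` with a warning then.
#'
#' @param pred Predicted values (GEBVs).
#' @param ref Reference values.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
accuracy <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(pred) < 3) stop("accuracy needs at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(pred, ref)
}
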