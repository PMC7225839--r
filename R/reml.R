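#' REML variance components on a genomic relationship matrix
#'
#' Estimates additive and residual variance for the intercept-only animal
#' model `y = 1 mu + g + e`, `g ~ N(0, K sigma_A^2)`, `e ~ N(0, I sigma_e^2)`
#' by restricted maximum likelihood. The restricted likelihood is profiled
#' down to the single variance ratio `delta = sigma_e^2 / sigma_A^2` via one
#' spectral decomposition of the projected kinship (the EMMA construction),
#' then maximized by Brent search on `log(delta)` over \[-10, 10\].
#' Narrow-sense heritability is `h2 = V_A / (V_A + V_e)`.
#'
#' @param y Phenotype vector, one entry per line of `K` (typically genotype
#'   lsmeans across environments).
#' @param K A [grm()] object or bare symmetric relationship matrix.
#' @param tol Convergence tolerance of the Brent search on `log(delta)`.
#' @return An object of class `varcomp`: `V_A` (population additive
#'   variance, `mean(diag(K))` times the K-scale coefficient `sigma_K`),
#'   `V_e` (residual variance), `sigma_K`, `lambda` (the variance ratio
#'   `V_e / sigma_K` used in the ridge equations), `h2`, `logREML`, `n`.
#'   For outbred-scaled kinships (`mean(diag(K)) ~ 1`) `V_A` and `sigma_K`
#'   coincide; for fully inbred material the diagonal averages ~2 and the
#'   distinction matters.
#' @export
reml <- function(y, K, tol = 1e-8) {
  Km <- if (inherits(K, "grm")) K$mat else as.matrix(K)
  n <- length(y)
  if (nrow(Km) != n || ncol(Km) != n)
    stop("K must be n x n with n = length(y)")
  if (any(!is.finite(y))) stop("y must be finite")
  if (stats::var(y) == 0)
    stop("y is constant: variance components are unidentifiable")
  if (max(abs(Km - t(Km))) > 1e-8 * max(1, max(abs(Km))))
    stop("K must be symmetric")
  sp <- reml_spectral(y, Km)
  obj <- function(logd) reml_profile_ll(exp(logd), sp)
  op <- stats::optimize(obj, interval = c(-10, 10), maximum = TRUE, tol = tol)
  # guard the interval ends: optimize() can miss a boundary optimum
  cand <- c(op$maximum, -10, 10)
  lls <- vapply(cand, obj, numeric(1))
  logd <- cand[which.max(lls)]
  delta <- exp(logd)
  q <- sp$q
  s1 <- sum(sp$eta2 / (sp$xi + delta))
  sigma_K <- s1 / q            # variance coefficient on the K scale
  V_e <- delta * sigma_K
  ## population additive variance: an individual's genetic variance is
  ## diag(K)_i * sigma_K, and for inbred material the VanRaden diagonal
  ## averages ~2 (relationship 1 + F), so V_A must carry that factor for
  ## h2 = V_A / (V_A + V_e) to be the phenotypic variance ratio
  d_bar <- mean(diag(Km))
  V_A <- d_bar * sigma_K
  structure(list(V_A = V_A, V_e = V_e, sigma_K = sigma_K, lambda = delta,
                 h2 = V_A / (V_A + V_e), logREML = max(lls), n = n),
            class = "varcomp")
}

## one-off spectral pieces: eigendecomposition restricted to the complement
## of the intercept. Decomposing S (K + I) S rather than S K S keeps the
## span-of-1 direction (eigenvalue 0) cleanly separated from genuine null
## directions of a rank-deficient K (eigenvalue 1), which SKS would mix.
reml_spectral <- function(y, Km) {
  n <- length(y)
  M <- Km
  diag(M) <- diag(M) + 1
  M <- M - matrix(colMeans(M), n, n, byrow = TRUE)
  M <- M - matrix(rowMeans(M), n, n)
  eg <- eigen(M, symmetric = TRUE)
  q <- n - 1L
  xi <- eg$values[seq_len(q)] - 1
  tol_psd <- 1e-6 * max(1, abs(xi[1]))
  if (min(xi) < -tol_psd)
    stop("K is not positive semi-definite (eigenvalue ",
         format(min(xi)), ")")
  xi <- pmax(xi, 0)
  U <- eg$vectors[, seq_len(q), drop = FALSE]
  eta <- drop(crossprod(U, y))
  list(q = q, xi = xi, eta2 = eta^2)
}

## profiled restricted log-likelihood at variance ratio delta = Ve/VA
reml_profile_ll <- function(delta, sp) {
  s1 <- sum(sp$eta2 / (sp$xi + delta))
  0.5 * (sp$q * log(sp$q / (2 * pi)) - sp$q -
           sp$q * log(s1) - sum(log(sp$xi + delta)))
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML variance components (GBLUP animal model)\n")
  cat(sprintf("  V_A = %.4f  V_e = %.4f  h2 = %.3f\n", x$V_A, x$V_e, x$h2))
  cat(sprintf("  lambda (Ve/VA) = %.4g  logREML = %.4f  n = %d\n",
              x$lambda, x$logREML, x$n))
  invisible(x)
}
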