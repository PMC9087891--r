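## Boundary clamping for density evaluation only: posterior CIs for phi can
## include 0 or 1 exactly, where beta/gamma log densities diverge.  Stored
## sample values are never modified.
.PHI_EPS <- 1e-9
.THETA_EPS <- 1e-12

.clampPhi <- function(x) pmin(pmax(x, .PHI_EPS), 1 - .PHI_EPS)
.clampTheta <- function(x) pmax(x, .THETA_EPS)

.dbetaLog <- function(x, p, q)
  (p - 1) * log(x) + (q - 1) * log1p(-x) - lbeta(p, q)

.dgammaLog <- function(x, a, b)
  a * log(b) - lgamma(a) + (a - 1) * log(x) - b * x

#' Maximum-likelihood fit of a beta distribution
#'
#' The beta log likelihood depends on the data only through the sufficient
#' statistics \eqn{\sum_t \log \xi_t} and \eqn{\sum_t \log(1-\xi_t)}.  The
#' MLE is found by quasi-Newton (BFGS) optimization of the two-parameter
#' profile on the log scale, started from the moment-matching estimates.
#' Values are clamped to \eqn{[10^{-9}, 1-10^{-9}]} before fitting.
#'
#' @param values sample in \eqn{(0, 1)} (boundary values are clamped).
#' @return named vector \code{c(p, q)} of shape parameters.
#' @export
fitBetaML <- function(values) {
  x <- .clampPhi(values)
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L)
    stop("need at least two distinct values to fit a beta distribution")
  S1 <- sum(log(x)); S2 <- sum(log1p(-x))
  m <- mean(x); v <- stats::var(x)
  cc <- max(m * (1 - m) / v - 1, 1e-3)
  start <- log(pmax(c(m * cc, (1 - m) * cc), 1e-3))
  nll <- function(lp) {
    p <- exp(lp[1]); q <- exp(lp[2])
    -((p - 1) * S1 + (q - 1) * S2 - n * lbeta(p, q))
  }
  gr <- function(lp) {
    p <- exp(lp[1]); q <- exp(lp[2])
    dpq <- digamma(p + q)
    c(-p * (S1 - n * (digamma(p) - dpq)),
      -q * (S2 - n * (digamma(q) - dpq)))
  }
  fit <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  out <- exp(fit$par)
  names(out) <- c("p", "q")
  out
}

#' Maximum-likelihood fit of a gamma distribution
#'
#' The gamma log likelihood depends on the data only through
#' \eqn{\sum_t \xi_t} and \eqn{\sum_t \log \xi_t}.  Profiling out the rate
#' (\eqn{b = a/\bar\xi} at the optimum) reduces the problem to a 1-D root
#' find for the shape, solved by Newton steps on
#' \eqn{\log a - \psi(a) = \log\bar\xi - \overline{\log \xi}}; the fitted
#' mean \eqn{a/b} therefore equals the sample mean exactly.
#'
#' @param values positive sample.
#' @return named vector \code{c(a, b)} (shape, rate).
#' @export
fitGammaML <- function(values) {
  if (any(values <= 0)) stop("gamma fitting needs positive values")
  x <- .clampTheta(values)
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("need at least two distinct values to fit a gamma distribution")
  m <- mean(x)
  s <- log(m) - mean(log(x))          # > 0 by Jensen for nondegenerate x
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(a) - digamma(a) - s
    if (abs(f) < 1e-12) break
    a <- a - f / (1 / a - trigamma(a))
    if (a <= 0) a <- 1e-8
  }
  c(a = a, b = a / m)
}

## Fit the per-column densities of one relabeling pass.  `M` has canonical
## column names (phi_* / theta_*); family selects beta/gamma densities or
## their normal replacements (per-column or pooled variance).
.fitColumns <- function(M, family) {
  cols <- colnames(M)
  fit <- vector("list", length(cols))
  names(fit) <- cols
  if (family == "betagamma") {
    for (j in seq_along(cols)) {
      fit[[j]] <- if (startsWith(cols[j], "phi_"))
        list(dist = "beta", par = fitBetaML(M[, j]))
      else list(dist = "gamma", par = fitGammaML(M[, j]))
    }
  } else {
    v <- apply(M, 2, stats::var)
    v[!is.finite(v) | v <= 0] <- .THETA_EPS
    if (family == "normal-pooled") v[] <- mean(v)
    for (j in seq_along(cols))
      fit[[j]] <- list(dist = "normal",
                       par = c(mean = mean(M[, j]), sd = sqrt(v[j])))
  }
  class(fit) <- "betaGammaFit"
  fit
}

## Row-wise log likelihood of a matrix under a .fitColumns() fit.
.loglikRows <- function(M, fit) {
  ll <- numeric(nrow(M))
  for (j in colnames(M)) {
    f <- fit[[j]]
    ll <- ll + switch(f$dist,
      beta = .dbetaLog(.clampPhi(M[, j]), f$par[1], f$par[2]),
      gamma = .dgammaLog(.clampTheta(M[, j]), f$par[1], f$par[2]),
      normal = stats::dnorm(M[, j], f$par[1], f$par[2], log = TRUE))
  }
  ll
}

#' Beta-gamma log likelihood of a labelled sample table
#'
#' Evaluates \eqn{\ell(\omega, z) = \sum_t \log f(z_t(\Theta_t); \omega)},
#' the sum over rows of independent beta log densities for the phi columns
#' and gamma log densities for the theta columns, at the transformed rows
#' selected by the labels.
#'
#' @param table sample table (data.frame).
#' @param labels integer vector of transform indicators \eqn{z_t}.
#' @param fit per-column density fit as returned by [fitTowerDensities()].
#' @param mappings list of [TowerMapping-class] transforms (identity first).
#' @param colmap optional named character vector mapping canonical parameter
#'   names to table column names.
#' @return scalar log likelihood.
#' @export
betaGammaLoglik <- function(table, labels, fit, mappings, colmap = NULL) {
  M <- .eventMatrix(table, mappings, colmap)
  images <- lapply(mappings, function(mp) .applyMappingMat(M, mp))
  ll <- 0
  for (z in seq_along(mappings) - 1L) {
    rows <- which(labels == z)
    if (length(rows))
      ll <- ll + sum(.loglikRows(images[[z + 1L]][rows, , drop = FALSE], fit))
  }
  ll
}

#' Fit beta/gamma densities to the labelled positions of a sample table
#'
#' Convenience wrapper: transforms each row by the mapping its label selects
#' and fits a beta distribution (ML) to every phi column and a gamma
#' distribution to every theta column.
#'
#' @inheritParams betaGammaLoglik
#' @return a \code{betaGammaFit}: named list with one \code{(dist, par)}
#'   entry per column.
#' @export
fitTowerDensities <- function(table, labels, mappings, colmap = NULL) {
  M <- .eventMatrix(table, mappings, colmap)
  C <- .selectImages(lapply(mappings, function(mp) .applyMappingMat(M, mp)),
                     labels)
  .fitColumns(C, "betagamma")
}
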