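#' Specification of a synthetic label-switching posterior sample
#'
#' Describes an MCMC-like sample with tower structure: within the reference
#' tower every phi column follows a beta distribution and every theta column
#' a gamma distribution; the other towers are realized by drawing from the
#' reference densities and applying the corresponding tower mapping.  The
#' chain of true tower labels is a Markov process that stays put with
#' probability \code{stay} and otherwise redraws the tower from the
#' stationary weights, emulating a posterior sampler that occasionally jumps
#' between symmetric modes.
#'
#' The defaults emulate the single-BDI simulation condition with true
#' introgression probabilities \eqn{(\phi_X, \phi_Y) = (0.7, 0.2)} at
#' moderate posterior concentration (beta shapes summing to 10) and parental
#' population sizes \eqn{\theta_X = 0.005}, \eqn{\theta_Y = 0.02} (gamma
#' shape 4), with two equal-weight towers and stay probability 0.999.
#'
#' @param phi named list of beta parameter pairs \code{c(p, q)}, one per phi
#'   column of the reference tower.
#' @param theta named list of gamma parameter pairs \code{c(a, b)} (shape,
#'   rate), one per theta column.
#' @param weights tower stationary weights (recycled/normalized to sum 1).
#' @param stay per-step probability that the label chain keeps its tower.
#' @param n number of draws.
#' @return a list of class \code{"towerSpec"}.
#' @seealso [simulateLabelSwitchingSamples()]
#' @export
towerSpec <- function(phi = list(phi_X = c(7, 3), phi_Y = c(2, 8)),
                      theta = list(theta_X = c(4, 800),
                                   theta_Y = c(4, 200)),
                      weights = c(0.5, 0.5), stay = 0.999, n = 200000L) {
  stopifnot(length(phi) >= 1L, length(stay) == 1L,
            stay >= 0, stay <= 1, length(n) == 1L, n >= 1L,
            all(unlist(phi) > 0), all(unlist(theta) > 0),
            all(weights > 0))
  spec <- list(phi = phi, theta = theta,
               weights = weights / sum(weights), stay = stay,
               n = as.integer(n))
  class(spec) <- "towerSpec"
  spec
}

#' Simulate an MCMC-like sample table with label switching
#'
#' Draws \code{spec$n} rows: the true tower label follows the Markov
#' switching process of the spec (started from its stationary distribution),
#' each row is drawn from the reference-tower beta/gamma densities, and rows
#' whose true tower is \eqn{z} are pushed through \code{mappings[[z + 1]]}.
#' Within a tower the marginals therefore follow the mapped reference laws
#' exactly, while the unprocessed mixture is symmetric when the mappings
#' mirror the reference densities.
#'
#' @param spec a [towerSpec()].
#' @param mappings list of [TowerMapping-class] transforms, identity first;
#'   its length sets the number of towers and must match
#'   \code{length(spec$weights)}.
#' @param seed integer seed for reproducibility (applied via a local RNG
#'   stream).
#' @return list with elements \code{samples} (data.frame with the phi and
#'   theta columns of the spec) and \code{labels} (integer vector of true
#'   tower labels).
#' @export
simulateLabelSwitchingSamples <- function(spec, mappings, seed = 1L) {
  stopifnot(inherits(spec, "towerSpec"))
  T <- length(mappings)
  if (length(spec$weights) != T)
    stop("spec has ", length(spec$weights), " tower weights but ",
         T, " mappings were supplied")
  n <- spec$n
  set.seed(as.integer(seed %% .Machine$integer.max))

  ## Markov label chain started at stationarity
  w <- spec$weights
  z <- integer(n)
  z[1] <- sample.int(T, 1L, prob = w) - 1L
  if (n > 1L) {
    jump <- stats::runif(n - 1L) >= spec$stay
    redraw <- sample.int(T, n - 1L, replace = TRUE, prob = w) - 1L
    for (t in 2:n)
      z[t] <- if (jump[t - 1L]) redraw[t - 1L] else z[t - 1L]
  }

  cols <- c(names(spec$phi), names(spec$theta))
  M <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (nm in names(spec$phi))
    M[, nm] <- stats::rbeta(n, spec$phi[[nm]][1], spec$phi[[nm]][2])
  for (nm in names(spec$theta))
    M[, nm] <- stats::rgamma(n, shape = spec$theta[[nm]][1],
                             rate = spec$theta[[nm]][2])
  for (t in seq_len(T) - 1L) {
    rows <- which(z == t)
    if (t > 0L && length(rows))
      M[rows, ] <- .applyMappingMat(M[rows, , drop = FALSE],
                                    mappings[[t + 1L]])
  }
  list(samples = as.data.frame(M), labels = z)
}
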