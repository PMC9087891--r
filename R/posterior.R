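#' Read an MCMC sample table
#'
#' Reads a tab-separated table with a header row of parameter names.  The
#' bpp \code{mcmc.txt} dialect is accepted: a leading generation-index
#' column (header \code{Gen}, case-insensitive) is kept in the table but
#' flagged so that [summarizeSamples()] excludes it.
#'
#' @param path path to a TSV file.
#' @return data.frame of finite numeric draws with preserved column order;
#'   attribute \code{"genColumn"} names the generation column when present.
#' @export
readSamples <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty sample file: ", path)
  if (anyDuplicated(names(df))) stop("duplicated column names in ", path)
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop("non-numeric or non-finite value at row ", bad[1],
           ", column '", names(df)[j], "'")
    df[[j]] <- x
  }
  if (grepl("^gen(eration)?$", names(df)[1], ignore.case = TRUE))
    attr(df, "genColumn") <- names(df)[1]
  df
}

#' Write an MCMC sample table
#'
#' Writes the tab-separated dialect read by [readSamples()], with full
#' precision so that a read/write cycle is bit-exact.
#'
#' @param table data.frame of draws.
#' @param path output path.
#' @export
writeSamples <- function(table, path) {
  out <- vapply(table, function(x) formatC(x, format = "g", digits = 17),
                character(nrow(table)))
  if (nrow(table) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(table)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Highest-posterior-density interval
#'
#' The shortest contiguous window of \eqn{\lceil \mathrm{level} \cdot N
#' \rceil} order statistics; ties are broken by the smallest lower endpoint.
#'
#' @param values numeric sample, \eqn{N \ge 2} (a constant sample yields a
#'   zero-width interval).
#' @param level coverage level in \eqn{(0, 1)}.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
hpdInterval <- function(values, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  x <- sort(values)
  n <- length(x)
  k <- ceiling(level * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)            # which.min takes the first (smallest) start
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Effective sample size
#'
#' \eqn{\mathrm{ESS} = N / (1 + 2 \sum_k \hat\rho_k)} with the
#' autocorrelation sum truncated by Geyer's initial-positive-sequence rule
#' (summation stops before the first nonpositive pairwise sum
#' \eqn{\hat\rho_{2k} + \hat\rho_{2k+1}}), clipped to \eqn{[1, N]}.
#'
#' @param values numeric sample, \eqn{N \ge 10}.
#' @return scalar effective sample size.
#' @export
ess <- function(values) {
  n <- length(values)
  if (n < 10L) stop("need at least 10 draws to estimate ESS")
  if (stats::var(values) == 0) {
    warning("constant sequence; ESS reported as N")
    return(n)
  }
  maxLag <- min(n - 1L, 10000L)
  rho <- stats::acf(values, lag.max = maxLag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(max(n / (1 + 2 * s), 1), n)
}

.bimodalPhi <- function(x) {
  ## advisory dip heuristic for a [0,1]-bounded column: mass depleted in the
  ## middle decile while both flanks carry substantial mass; needs enough
  ## draws to be meaningful
  if (length(x) < 200L) return(FALSE)
  pLo <- mean(x < 0.45)
  pHi <- mean(x > 0.55)
  pMid <- 1 - pLo - pHi
  pLo >= 0.25 && pHi >= 0.25 && pMid <= 0.05
}

#' Summarize an MCMC sample table
#'
#' Per-column posterior mean, 95\% HPD interval, and effective sample size.
#' The table should already be relabeled; a warning is emitted when a
#' \eqn{[0,1]}-bounded column looks bimodal by a dip heuristic, which is the
#' signature of unprocessed label switching.  A generation-index column
#' flagged by [readSamples()] is excluded.
#'
#' @param table data.frame of draws.
#' @param level HPD coverage level.
#' @return data.frame with columns \code{name}, \code{mean}, \code{hpd_lo},
#'   \code{hpd_hi}, \code{ess}, \code{n}.
#' @export
summarizeSamples <- function(table, level = 0.95) {
  gen <- attr(table, "genColumn")
  cols <- setdiff(names(table), gen)
  out <- data.frame(name = cols, mean = NA_real_, hpd_lo = NA_real_,
                    hpd_hi = NA_real_, ess = NA_real_,
                    n = nrow(table), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    x <- table[[cols[i]]]
    out$mean[i] <- mean(x)
    h <- hpdInterval(x, level)
    out$hpd_lo[i] <- h[1]
    out$hpd_hi[i] <- h[2]
    out$ess[i] <- if (nrow(table) < 10L || stats::var(x) == 0) {
      nrow(table)
    } else ess(x)
    if (min(x) >= 0 && max(x) <= 1 && .bimodalPhi(x))
      warning("column '", cols[i], "' looks bimodal; ",
              "was the sample relabeled?", call. = FALSE)
  }
  out
}
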