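## ABBA-BABA site-pattern statistics for a species quartet
## ((S1, S2), S3) plus outgroup O, computed from genome-wide site-pattern
## counts.  These genome-wide-average heuristics contrast with the
## full-likelihood treatment: they can test for gene flow between nonsister
## species but carry no information about its direction or timing, and none
## about gene flow between sister species.

.alnMatrix <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    M <- as.character(alignment)
    if (!is.matrix(M)) {
      if (length(unique(lengths(M))) != 1L)
        stop("sequences must have equal length")
      M <- do.call(rbind, M)
    }
    M <- toupper(M)
  } else if (is.matrix(alignment)) {
    M <- toupper(alignment)
  } else if (is.list(alignment) || is.character(alignment)) {
    seqs <- lapply(alignment, function(s)
      if (length(s) == 1L) strsplit(toupper(s), "")[[1]] else toupper(s))
    if (length(unique(lengths(seqs))) != 1L)
      stop("sequences must have equal length")
    M <- do.call(rbind, seqs)
  } else stop("unsupported alignment type")
  if (nrow(M) < 4L) stop("need four sequences in order S1, S2, S3, O")
  M[1:4, , drop = FALSE]
}

#' Count parsimony-informative site patterns
#'
#' For four equal-length sequences in the order S1, S2, S3, O counts the
#' three parsimony-informative patterns: \emph{BBAA} (S1 and S2 share one
#' nucleotide while S3 and O share another), \emph{ABBA} (S2 with S3) and
#' \emph{BABA} (S1 with S3).  Only sites with exactly two distinct
#' \code{A/C/G/T} states split 2/2 are counted; sites containing gaps,
#' ambiguity codes or three or more alleles are ignored.
#'
#' @param alignment four sequences as a \code{DNAbin} object (e.g. from
#'   \code{ape::read.FASTA}), a character matrix, or a list/vector of
#'   strings, ordered S1, S2, S3, O.
#' @return named integer vector \code{c(nABBA, nBABA, nBBAA)}.
#' @seealso [dStatistic()], [hydePhi()]
#' @export
countSitePatterns <- function(alignment) {
  M <- .alnMatrix(alignment)
  ok <- colSums(matrix(M %in% c("A", "C", "G", "T"), nrow = 4L)) == 4L
  M <- M[, ok, drop = FALSE]
  eq12 <- M[1, ] == M[2, ]; eq34 <- M[3, ] == M[4, ]
  eq23 <- M[2, ] == M[3, ]; eq14 <- M[1, ] == M[4, ]
  eq13 <- M[1, ] == M[3, ]; eq24 <- M[2, ] == M[4, ]
  two <- (eq12 & eq34 & !eq13) | (eq23 & eq14 & !eq12) | (eq13 & eq24 & !eq12)
  c(nABBA = sum(two & eq23 & eq14),
    nBABA = sum(two & eq13 & eq24),
    nBBAA = sum(two & eq12 & eq34))
}

#' The D statistic (ABBA-BABA test)
#'
#' \eqn{D = (n_{ABBA} - n_{BABA}) / (n_{ABBA} + n_{BABA})}.  Under the
#' species tree with no gene flow the two mismatching patterns have the
#' same probability and \eqn{D = 0}; gene flow between S3 and one of
#' S1/S2 skews the counts.
#'
#' @param counts named vector/list with \code{nABBA} and \code{nBABA}
#'   (e.g. from [countSitePatterns()]).
#' @return \eqn{D \in [-1, 1]}, or \code{NA} with a warning when
#'   \eqn{n_{ABBA} + n_{BABA} = 0}.
#' @export
dStatistic <- function(counts) {
  a <- counts[["nABBA"]]; b <- counts[["nBABA"]]
  if (a + b == 0) {
    warning("nABBA + nBABA is zero; D undefined")
    return(NA_real_)
  }
  (a - b) / (a + b)
}

#' Site-pattern estimate of the introgression probability
#'
#' \eqn{\hat\varphi = (n_{BBAA} - n_{BABA}) /
#' (n_{BBAA} - 2 n_{BABA} + n_{ABBA})}, derived under a hybrid-speciation
#' model with symmetric divergence times and population sizes; the estimate
#' can be biased when that symmetry does not hold.
#'
#' @param counts named vector/list with \code{nABBA}, \code{nBABA} and
#'   \code{nBBAA}.
#' @return \eqn{\hat\varphi}, or \code{NA} with a warning when the
#'   denominator is zero.
#' @export
hydePhi <- function(counts) {
  a <- counts[["nABBA"]]; b <- counts[["nBABA"]]; s <- counts[["nBBAA"]]
  den <- s - 2 * b + a
  if (den == 0) {
    warning("denominator nBBAA - 2 nBABA + nABBA is zero; phi undefined")
    return(NA_real_)
  }
  (s - b) / den
}
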