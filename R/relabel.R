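## Shared machinery for the relabeling passes.  A pass works on the event
## columns only: canonical parameter names (phi_*, theta_*) are resolved to
## table columns through `colmap` (identity by default).

.eventColumns <- function(mappings) {
  cols <- Reduce(union, lapply(mappings, function(mp) mp@target))
  if (is.null(cols) || !length(cols))
    stop("the transform list contains no non-identity mapping")
  cols
}

.resolveColumns <- function(cols, colmap, tableNames) {
  resolved <- if (is.null(colmap)) cols else {
    miss <- setdiff(cols, names(colmap))
    if (length(miss))
      stop("colmap does not map parameter(s): ", paste(miss, collapse = ", "))
    unname(colmap[cols])
  }
  absent <- setdiff(resolved, tableNames)
  if (length(absent))
    stop("sample table lacks column(s): ", paste(absent, collapse = ", "))
  resolved
}

.eventMatrix <- function(table, mappings, colmap = NULL) {
  cols <- .eventColumns(mappings)
  resolved <- .resolveColumns(cols, colmap, names(table))
  M <- as.matrix(table[, resolved, drop = FALSE])
  if (!is.numeric(M) || any(!is.finite(M)))
    stop("event columns must be finite numeric")
  colnames(M) <- cols
  M
}

.selectImages <- function(images, labels) {
  C <- images[[1L]]
  for (z in seq_along(images) - 1L) {
    rows <- labels == z
    if (z > 0L && any(rows)) C[rows, ] <- images[[z + 1L]][rows, , drop = FALSE]
  }
  C
}

## Initialization preferring the tower with small introgression
## probabilities.  Two transforms: the printed rule z = 0 iff
## phiX + phiY < 1, else 1.  Four transforms (double-BDI): lowest index
## whose image satisfies phiX+phiY < 1, then phiZ+phiW < 1; if none
## satisfies the first criterion, the lowest index minimizing phiX+phiY.
.initLabelsImages <- function(images, mappings) {
  N <- nrow(images[[1L]])
  phiCols <- grep("^phi_", colnames(images[[1L]]), value = TRUE)
  if (length(images) == 2L) {
    s <- rowSums(images[[1L]][, phiCols, drop = FALSE])
    return(as.integer(s >= 1))
  }
  ## lower-event phis: the complement of the phi targets of transform z=1
  upPhis <- grep("^phi_", mappings[[2L]]@target, value = TRUE)
  loPhis <- setdiff(phiCols, upPhis)
  T <- length(images)
  sLo <- vapply(images, function(I) rowSums(I[, loPhis, drop = FALSE]), numeric(N))
  sUp <- vapply(images, function(I) rowSums(I[, upPhis, drop = FALSE]), numeric(N))
  z <- integer(N)
  for (t in seq_len(N)) {
    ok1 <- which(sLo[t, ] < 1)
    if (length(ok1)) {
      ok2 <- ok1[sUp[t, ok1] < 1]
      z[t] <- if (length(ok2)) ok2[1L] - 1L else ok1[1L] - 1L
    } else {
      cand <- which(sLo[t, ] == min(sLo[t, ]))
      cand <- cand[sUp[t, cand] == min(sUp[t, cand])]
      z[t] <- cand[1L] - 1L
    }
  }
  z
}

#' Initial transform labels for a relabeling pass
#'
#' Implements the initialization rule: a row starts on the original tower
#' (\eqn{z_t = 0}) when \eqn{\phi_X + \phi_Y < 1} and on the mirror tower
#' otherwise; with four transforms the preferred tower is the one with small
#' introgression probabilities (see Details in [betaGammaRelabel()]).
#'
#' @param table sample table (data.frame).
#' @param event a [BDIEvent-class], or a list of [TowerMapping-class]
#'   transforms.
#' @param colmap optional canonical-name-to-column mapping.
#' @return integer vector of labels.
#' @export
initLabels <- function(table, event, colmap = NULL) {
  mappings <- if (is(event, "BDIEvent"))
    list(identityMapping(), singleBdiMapping(event)) else event
  M <- .eventMatrix(table, mappings, colmap)
  images <- lapply(mappings, function(mp) .applyMappingMat(M, mp))
  .initLabelsImages(images, mappings)
}

#' Distance of a sample point from a center of gravity
#'
#' Euclidean distance \eqn{d_0(\Theta_t, \mu) =
#' [\sum_j (\xi_j - \mu_j)^2]^{1/2}} (CoG0), or the variance-normalized
#' distance \eqn{d_N} with per-coordinate weights \eqn{1/\nu_j} (CoGN).
#'
#' @param point,center equal-length numeric vectors.
#' @param weights optional per-coordinate variances \eqn{\nu_j > 0}; when
#'   given the squared differences are divided by them.
#' @return nonnegative scalar.
#' @export
towerDistance <- function(point, center, weights = NULL) {
  if (length(point) != length(center))
    stop("point and center must have the same length")
  d2 <- (point - center)^2
  if (!is.null(weights)) {
    if (length(weights) != length(point))
      stop("weights must match the point length")
    if (any(weights <= 0)) stop("weights must be positive")
    d2 <- d2 / weights
  }
  sqrt(sum(d2))
}

.relabelResult <- function(table, M, images, labels, cols, resolved,
                           iterations, objective, algorithm, mappings) {
  C <- .selectImages(images, labels)
  out <- table
  out[, resolved] <- C[, cols, drop = FALSE]
  new("RelabelResult", samples = out, labels = as.integer(labels),
      iterations = as.integer(iterations), objective = objective,
      algorithm = algorithm, mappings = mappings)
}

#' Center-of-gravity relabeling (CoG0 / CoGN)
#'
#' Iterates two steps until no label changes: (1) compute the center of
#' gravity \eqn{\mu} (and, for CoGN, the per-coordinate variances
#' \eqn{\nu}) over the currently selected positions; (2) move every sample
#' point to whichever of its transform images is closest to \eqn{\mu} under
#' [towerDistance()] (current label kept on exact ties).  For CoG0 the
#' recorded objective \eqn{\sum_t d_0^2} is nonincreasing.
#'
#' @param table sample table (data.frame of finite numeric draws).
#' @param mappings list of [TowerMapping-class] transforms, identity first
#'   (2 for a single BDI event, 4 for a stacked double-BDI pair).
#' @param colmap optional named character vector mapping canonical parameter
#'   names (\code{phi_X}, ...) to table column names.
#' @param normalized use variance-normalized distances (CoGN)?
#' @param maxIter iteration cap (a warning is issued when reached).
#' @return a [RelabelResult-class].
#' @export
cogRelabel <- function(table, mappings, colmap = NULL, normalized = FALSE,
                       maxIter = 1000L) {
  cols <- .eventColumns(mappings)
  resolved <- .resolveColumns(cols, colmap, names(table))
  M <- .eventMatrix(table, mappings, colmap)
  N <- nrow(M)
  if (N < 1L) stop("empty sample table")
  images <- lapply(mappings, function(mp) .applyMappingMat(M, mp))
  z <- .initLabelsImages(images, mappings)
  objective <- numeric()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    C <- .selectImages(images, z)
    mu <- colMeans(C)
    w <- if (normalized) {
      v <- apply(C, 2, stats::var)
      v[!is.finite(v) | v <= 0] <- 1
      v
    } else rep(1, ncol(C))
    D2 <- vapply(images, function(I)
      rowSums(sweep(sweep(I, 2, mu)^2, 2, w, `/`)), numeric(N))
    best <- max.col(-D2, ties.method = "first") - 1L
    cur <- D2[cbind(seq_len(N), z + 1L)]
    bst <- D2[cbind(seq_len(N), best + 1L)]
    newz <- ifelse(bst < cur, best, z)       # keep current label on ties
    objective <- c(objective, sum(D2[cbind(seq_len(N), newz + 1L)]))
    if (all(newz == z)) { z <- newz; break }
    z <- newz
    if (iter >= maxIter) {
      warning("cogRelabel: iteration cap reached before convergence")
      break
    }
  }
  .relabelResult(table, M, images, z, cols, resolved, iter, objective,
                 if (normalized) "cogn" else "cog0", mappings)
}

#' Beta-gamma relabeling
#'
#' Alternates (1) maximum-likelihood fitting of independent beta densities
#' to the phi columns and gamma densities to the theta columns of the
#' currently selected positions, and (2) per-row selection of the transform
#' image with the highest log density under the fitted model (current label
#' kept on exact ties), until no label changes.  The log likelihood
#' \eqn{\ell(\omega, z)} never decreases across half-steps.  With four
#' transforms (double-BDI) four beta and four gamma densities are fitted —
#' 16 distribution parameters, obtained as eight independent 2-D
#' optimizations.
#'
#' Setting \code{family = "normal-pooled"} replaces the beta/gamma densities
#' by normal densities with a common variance, which reproduces the CoG0
#' label choice; \code{family = "normal"} uses per-column variances and
#' corresponds to CoGN.
#'
#' @inheritParams cogRelabel
#' @param family density family: \code{"betagamma"} (default),
#'   \code{"normal"}, or \code{"normal-pooled"}.
#' @return a [RelabelResult-class]; the recorded objective is the
#'   (nondecreasing) log likelihood per iteration.
#' @export
betaGammaRelabel <- function(table, mappings, colmap = NULL,
                             family = c("betagamma", "normal",
                                        "normal-pooled"),
                             maxIter = 1000L) {
  family <- match.arg(family)
  cols <- .eventColumns(mappings)
  resolved <- .resolveColumns(cols, colmap, names(table))
  M <- .eventMatrix(table, mappings, colmap)
  N <- nrow(M)
  if (N < 1L) stop("empty sample table")
  images <- lapply(mappings, function(mp) .applyMappingMat(M, mp))
  z <- .initLabelsImages(images, mappings)
  objective <- numeric()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    C <- .selectImages(images, z)
    fit <- .fitColumns(C, family)
    LL <- vapply(images, function(I) .loglikRows(I, fit), numeric(N))
    best <- max.col(LL, ties.method = "first") - 1L
    cur <- LL[cbind(seq_len(N), z + 1L)]
    bst <- LL[cbind(seq_len(N), best + 1L)]
    newz <- ifelse(bst > cur, best, z)       # keep current label on ties
    objective <- c(objective, sum(LL[cbind(seq_len(N), newz + 1L)]))
    if (all(newz == z)) { z <- newz; break }
    z <- newz
    if (iter >= maxIter) {
      warning("betaGammaRelabel: iteration cap reached before convergence")
      break
    }
  }
  algo <- if (family == "betagamma") "betagamma"
          else paste0("betagamma-", family)
  .relabelResult(table, M, images, z, cols, resolved, iter, objective,
                 algo, mappings)
}

#' Result of relabeling every sister BDI event of a model
#'
#' @slot table the fully processed sample table.
#' @slot passes named list of per-event [RelabelResult-class] objects, in
#'   processing order.
#' @slot nonsister names of nonsister BDI events, which are reported but not
#'   relabeled (a fixed-model MCMC visits a single model variant; mapping
#'   between variants is a topology edit, see [enumerateTowers()]).
#' @slot algorithm the algorithm applied.
#' @export
setClass("RelabelSweep", representation(
  table = "data.frame", passes = "list", nonsister = "character",
  algorithm = "character"))

#' Relabel all sister BDI events of a model, sequentially
#'
#' Applies the chosen relabeling algorithm once per sister BDI event — or
#' once, with four transforms, per stacked double-BDI pair — in ascending
#' order of event time (ties broken by node label).  Nonsister events are
#' reported, not relabeled.
#'
#' @param table sample table (data.frame).
#' @param model an [MSciModel-class].
#' @param algorithm \code{"cog0"}, \code{"cogn"} or \code{"betagamma"}.
#' @param colmap optional named character vector mapping the canonical
#'   parameter names of [modelParams()] to table column names (this is also
#'   the hook for renaming external sample headers, e.g. bpp-style
#'   \code{mcmc.txt} columns, under the package's phi convention).
#' @param maxIter per-pass iteration cap.
#' @return a [RelabelSweep-class].
#' @export
relabelAll <- function(table, model,
                       algorithm = c("cog0", "cogn", "betagamma"),
                       colmap = NULL, maxIter = 1000L) {
  algorithm <- match.arg(algorithm)
  events <- detectBdiEvents(model)
  sis <- Filter(function(e) e@sister, events)
  non <- Filter(function(e) !e@sister, events)

  units <- list()
  used <- rep(FALSE, length(sis))
  for (i in seq_along(sis)) {
    if (used[i]) next
    partner <- 0L
    for (j in seq_along(sis)) {
      if (j == i || used[j]) next
      if (isStackedPair(model, sis[[i]], sis[[j]])) { partner <- j; break }
    }
    if (partner > 0L) {
      used[c(i, partner)] <- TRUE
      units[[length(units) + 1L]] <- list(
        tau = sis[[i]]@tau,
        name = paste0(sis[[i]]@nodeX, "-", sis[[i]]@nodeY, "+",
                      sis[[partner]]@nodeX, "-", sis[[partner]]@nodeY),
        mappings = doubleBdiMappings(sis[[i]], sis[[partner]]))
    } else {
      used[i] <- TRUE
      units[[length(units) + 1L]] <- list(
        tau = sis[[i]]@tau,
        name = paste0(sis[[i]]@nodeX, "-", sis[[i]]@nodeY),
        mappings = list(identityMapping(), singleBdiMapping(sis[[i]])))
    }
  }
  if (length(units)) {
    ord <- order(vapply(units, `[[`, 0, "tau"),
                 vapply(units, `[[`, "", "name"))
    units <- units[ord]
  }

  passes <- list()
  for (u in units) {
    res <- switch(algorithm,
      cog0 = cogRelabel(table, u$mappings, colmap, normalized = FALSE,
                        maxIter = maxIter),
      cogn = cogRelabel(table, u$mappings, colmap, normalized = TRUE,
                        maxIter = maxIter),
      betagamma = betaGammaRelabel(table, u$mappings, colmap,
                                   maxIter = maxIter))
    table <- res@samples
    passes[[u$name]] <- res
  }
  new("RelabelSweep", table = table, passes = passes,
      nonsister = vapply(non, function(e)
        paste0(e@nodeX, "-", e@nodeY), ""),
      algorithm = algorithm)
}

#' Label accuracy up to tower permutation
#'
#' The mirror towers are equally correct answers, so accuracy is the maximum
#' over all global permutations of tower labels of the fraction of agreeing
#' labels.
#'
#' @param zEst,zTrue equal-length integer label vectors.
#' @return fraction in \eqn{[0, 1]}.
#' @export
relabelAccuracy <- function(zEst, zTrue) {
  if (length(zEst) != length(zTrue))
    stop("label vectors must have equal length")
  T <- max(zEst, zTrue) + 1L
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(T) - 1L))
    best <- max(best, mean(p[zEst + 1L] == zTrue))
  best
}

#' @describeIn RelabelResult-class summary of a relabeling pass
#' @param object a \code{RelabelResult}.
#' @export
setMethod("show", "RelabelResult", function(object) {
  cat(sprintf("RelabelResult [%s]: %d rows, %d transforms, %d iteration(s)\n",
              object@algorithm, nrow(object@samples),
              length(object@mappings), object@iterations))
  cat("  final objective:", format(utils::tail(object@objective, 1)), "\n")
  cat("  label counts:", paste(sprintf("z=%d: %d",
      seq_along(object@mappings) - 1L,
      tabulate(object@labels + 1L, length(object@mappings))),
      collapse = ", "), "\n")
  invisible(object)
})

#' @describeIn RelabelSweep-class summary of all passes
#' @param object a \code{RelabelSweep}.
#' @export
setMethod("show", "RelabelSweep", function(object) {
  cat(sprintf("RelabelSweep [%s]: %d pass(es)\n", object@algorithm,
              length(object@passes)))
  for (nm in names(object@passes)) {
    r <- object@passes[[nm]]
    cat(sprintf("  %s: %d iteration(s), %.3g%% of rows moved\n", nm,
                r@iterations, 100 * mean(r@labels != 0L)))
  }
  if (length(object@nonsister))
    cat("  nonsister event(s) reported, not relabeled:",
        paste(object@nonsister, collapse = ", "), "\n")
  invisible(object)
})
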