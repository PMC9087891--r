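.mapping <- function(target, source, complement, label = "",
                     topology = "same-model", events = character()) {
  new("TowerMapping", target = as.character(target),
      source = as.character(source), complement = as.logical(complement),
      label = label, topology = topology, events = events)
}

#' Identity tower mapping
#' @return a [TowerMapping-class] that leaves every parameter unchanged.
#' @export
identityMapping <- function()
  .mapping(character(), character(), logical(), label = "0")

#' Mirror mapping of a single BDI event
#'
#' The two towers of one BDI event are related by complementing the two
#' introgression probabilities and swapping the two parental population
#' sizes: \eqn{\phi_X' = 1-\phi_X}, \eqn{\phi_Y' = 1-\phi_Y},
#' \eqn{\theta_X' = \theta_Y}, \eqn{\theta_Y' = \theta_X}.  All other
#' parameters are copied unchanged.  The mapping is an involution.
#'
#' @param event a [BDIEvent-class] (or any object with a \code{params} slot
#'   naming \code{phi_X, phi_Y, theta_X, theta_Y} in that order).
#' @return a [TowerMapping-class].
#' @export
singleBdiMapping <- function(event) {
  p <- event@params
  topo <- if (event@sister) "same-model" else
    paste0("mirror:", event@nodeX, "-", event@nodeY)
  .mapping(target = p,
           source = c(p[1], p[2], p[4], p[3]),
           complement = c(TRUE, TRUE, FALSE, FALSE),
           label = "1", topology = topo,
           events = paste0(event@nodeX, "-", event@nodeY))
}

#' The four tower mappings of a stacked double-BDI pair
#'
#' Two successive BDI events between the same pair of lineages create four
#' within-model towers.  Writing \eqn{(\phi_X,\phi_Y,\theta_X,\theta_Y)} for
#' the lower (younger) event and \eqn{(\phi_Z,\phi_W,\theta_Z,\theta_W)} for
#' the upper event, the transforms indexed by \eqn{z = 0,\dots,3} are:
#' \describe{
#'   \item{z = 0}{identity.}
#'   \item{z = 1}{complement \eqn{\phi_Z, \phi_W}; swap
#'     \eqn{\theta_Z \leftrightarrow \theta_W}.}
#'   \item{z = 2}{complement \eqn{\phi_X, \phi_Y}; swap
#'     \eqn{\theta_X \leftrightarrow \theta_Y}; swap
#'     \eqn{\phi_Z \leftrightarrow \phi_W}; swap
#'     \eqn{\theta_Z \leftrightarrow \theta_W}.}
#'   \item{z = 3}{complement \eqn{\phi_X, \phi_Y}; swap
#'     \eqn{\theta_X \leftrightarrow \theta_Y};
#'     \eqn{\phi_Z' = 1-\phi_W}, \eqn{\phi_W' = 1-\phi_Z}.}
#' }
#' The four transforms form a Klein four-group under composition (each is
#' its own inverse).
#'
#' @param lower,upper [BDIEvent-class] objects for the younger and older
#'   event of the stacked pair.
#' @return list of four [TowerMapping-class] objects, \code{z = 0..3}.
#' @export
doubleBdiMappings <- function(lower, upper) {
  if (lower@tau >= upper@tau)
    stop("'lower' must be the younger event of the stacked pair")
  lo <- lower@params                     # phi_X phi_Y theta_X theta_Y
  up <- upper@params                     # phi_Z phi_W theta_Z theta_W
  evs <- c(paste0(lower@nodeX, "-", lower@nodeY),
           paste0(upper@nodeX, "-", upper@nodeY))
  z0 <- identityMapping()
  z0@events <- evs
  z1 <- .mapping(target = up, source = up[c(1, 2, 4, 3)],
                 complement = c(TRUE, TRUE, FALSE, FALSE),
                 label = "1", events = evs)
  z2 <- .mapping(target = c(lo, up),
                 source = c(lo[c(1, 2, 4, 3)], up[c(2, 1, 4, 3)]),
                 complement = c(TRUE, TRUE, FALSE, FALSE,
                                FALSE, FALSE, FALSE, FALSE),
                 label = "2", events = evs)
  z3 <- .mapping(target = c(lo, up[1:2]),
                 source = c(lo[c(1, 2, 4, 3)], up[c(2, 1)]),
                 complement = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
                 label = "3", events = evs)
  list(z0, z1, z2, z3)
}

#' Apply a tower mapping to a named parameter vector
#'
#' Parameters outside the mapping are copied unchanged.
#'
#' @param row named numeric vector (or single-row data.frame) containing all
#'   parameters named by the mapping.
#' @param mapping a [TowerMapping-class].
#' @return the transformed vector, same names and order as the input.
#' @export
applyMapping <- function(row, mapping) {
  isDf <- is.data.frame(row)
  x <- if (isDf) unlist(row[1, , drop = TRUE]) else row
  miss <- setdiff(unique(c(mapping@target, mapping@source)), names(x))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  out <- x
  v <- x[mapping@source]
  v[mapping@complement] <- 1 - v[mapping@complement]
  out[mapping@target] <- v
  if (isDf) {
    row[1, ] <- as.list(out)
    row
  } else out
}

## Apply a mapping to a numeric matrix whose columns are named parameters.
.applyMappingMat <- function(M, mapping) {
  if (!length(mapping@target)) return(M)
  V <- M[, mapping@source, drop = FALSE]
  if (any(mapping@complement))
    V[, mapping@complement] <- 1 - V[, mapping@complement, drop = FALSE]
  M[, mapping@target] <- V
  M
}

#' Compose two tower mappings
#'
#' Returns the mapping equivalent to applying \code{first}, then
#' \code{second}.
#'
#' @param first,second [TowerMapping-class] objects.
#' @return a [TowerMapping-class].
#' @export
composeMappings <- function(first, second) {
  tg <- union(second@target, first@target)
  src <- character(length(tg)); comp <- logical(length(tg))
  for (i in seq_along(tg)) {
    p <- tg[i]
    ## effect of `second` on p
    j <- match(p, second@target)
    if (is.na(j)) { s2 <- p; c2 <- FALSE } else {
      s2 <- second@source[j]; c2 <- second@complement[j]
    }
    ## then resolve s2 through `first`
    k <- match(s2, first@target)
    if (is.na(k)) { s1 <- s2; c1 <- FALSE } else {
      s1 <- first@source[k]; c1 <- first@complement[k]
    }
    src[i] <- s1
    comp[i] <- xor(c1, c2)
  }
  keep <- !(src == tg & !comp)
  .mapping(tg[keep], src[keep], comp[keep],
           label = paste0(first@label, "*", second@label),
           topology = if (identical(first@topology, "same-model") &&
                          identical(second@topology, "same-model"))
             "same-model" else "mirrored",
           events = union(first@events, second@events))
}

#' Enumerate the unidentifiable models and towers of an MSci model
#'
#' With \eqn{m} sister BDI events and \eqn{n} nonsister BDI events a model
#' has \eqn{2^n} unidentifiable model variants, each containing \eqn{2^m}
#' within-model towers.  Within-model mappings are built by composing the
#' event-wise involutions of [singleBdiMapping()]; a stacked double-BDI pair
#' contributes the four transforms of [doubleBdiMappings()] in place of two
#' independent sister mirrors.  Towers within a variant are ordered by
#' binary code over events with the youngest event as the least-significant
#' bit; nonsister mappings define the mirrored model variants and are
#' reported (topology edit plus parameter renames), not applied to sample
#' tables automatically.
#'
#' @param model an [MSciModel-class].
#' @return a [TowerSet-class].
#' @export
enumerateTowers <- function(model) {
  events <- detectBdiEvents(model)
  sis <- Filter(function(e) e@sister, events)
  non <- Filter(function(e) !e@sister, events)

  ## group sister events into units: stacked double-BDI pairs (4 transforms,
  ## 2 bits) and lone events (2 transforms, 1 bit); events are already in
  ## ascending time order, so units come out youngest-first
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
        bits = 2L, mappings = doubleBdiMappings(sis[[i]], sis[[partner]]))
    } else {
      used[i] <- TRUE
      units[[length(units) + 1L]] <- list(
        bits = 1L, mappings = list(identityMapping(),
                                   singleBdiMapping(sis[[i]])))
    }
  }

  m <- length(sis)
  n <- length(non)
  nTowers <- 2L^m

  towerMappings <- vector("list", nTowers)
  for (code in seq_len(nTowers) - 1L) {
    mp <- identityMapping()
    shift <- 0L
    for (u in units) {
      z <- bitwAnd(bitwShiftR(code, shift), 2L^u$bits - 1L)
      if (z > 0L) mp <- composeMappings(mp, u$mappings[[z + 1L]])
      shift <- shift + u$bits
    }
    mp@label <- paste0("tower-", code)
    towerMappings[[code + 1L]] <- mp
  }

  variants <- vector("list", 2L^n)
  nonNames <- vapply(non, function(e) paste0(e@nodeX, "-", e@nodeY), "")
  for (vcode in seq_len(2L^n) - 1L) {
    flip <- which(bitwAnd(bitwShiftR(vcode, seq_along(non) - 1L), 1L) == 1L)
    flipped <- nonNames[flip]
    tag <- if (vcode == 0L) "variant-0" else
      paste0("variant-", vcode, ":", paste(flipped, collapse = ","))
    vmaps <- towerMappings
    if (length(flip)) {
      edit <- Reduce(composeMappings,
                     lapply(non[flip], singleBdiMapping))
      vmaps <- lapply(vmaps, function(mp) {
        out <- composeMappings(mp, edit)
        out@label <- mp@label
        out@topology <- paste0("mirrored:", paste(flipped, collapse = ","))
        out
      })
    }
    variants[[vcode + 1L]] <- list(tag = tag, flipped = flipped,
                                   mappings = vmaps)
  }

  new("TowerSet", variants = variants, m = as.integer(m), n = as.integer(n))
}

#' Number of within-model towers per variant
#' @param towers a [TowerSet-class].
#' @return integer, \eqn{2^m}.
#' @export
towersPerVariant <- function(towers) length(towers@variants[[1]]$mappings)

#' Number of unidentifiable model variants
#' @param towers a [TowerSet-class].
#' @return integer, \eqn{2^n}.
#' @export
variantCount <- function(towers) length(towers@variants)

#' Within-model tower mappings of one variant
#' @param towers a [TowerSet-class].
#' @param variant 1-based variant index (1 = the input topology).
#' @return list of [TowerMapping-class] objects.
#' @export
towerMappings <- function(towers, variant = 1L)
  towers@variants[[variant]]$mappings

#' Tabulate a tower mapping
#' @param mapping a [TowerMapping-class].
#' @return data.frame with columns \code{parameter}, \code{transform}.
#' @export
mappingTable <- function(mapping) {
  if (!length(mapping@target))
    return(data.frame(parameter = character(), transform = character(),
                      stringsAsFactors = FALSE))
  tf <- ifelse(mapping@complement,
               paste0("1 - ", mapping@source),
               mapping@source)
  data.frame(parameter = mapping@target, transform = tf,
             stringsAsFactors = FALSE)
}

#' @describeIn TowerMapping-class display the per-parameter transforms
#' @param object a \code{TowerMapping}.
#' @export
setMethod("show", "TowerMapping", function(object) {
  cat("TowerMapping", object@label,
      if (!identical(object@topology, "same-model"))
        paste0("[", object@topology, "]") else "", "\n")
  tb <- mappingTable(object)
  if (nrow(tb) == 0L) cat("  identity\n")
  else for (i in seq_len(nrow(tb)))
    cat("  ", tb$parameter[i], "<-", tb$transform[i], "\n")
  invisible(object)
})

#' @describeIn TowerSet-class display counts and variants
#' @param object a \code{TowerSet}.
#' @export
setMethod("show", "TowerSet", function(object) {
  cat(sprintf(paste0("TowerSet: %d sister and %d nonsister BDI event(s) -> ",
                     "%d model variant(s) x %d within-model tower(s)\n"),
              object@m, object@n, variantCount(object),
              towersPerVariant(object)))
  for (v in object@variants)
    cat("  ", v$tag,
        if (length(v$flipped)) paste0(" (mirrors ",
                                      paste(v$flipped, collapse = ", "), ")")
        else "", "\n", sep = "")
  invisible(object)
})
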