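#' Validate an MSci model
#'
#' Checks every model invariant and returns all violations found (an empty
#' character vector means the model is valid).  Violations are data, not
#' errors, so that a structurally parseable but inconsistent model can be
#' inspected in full.
#'
#' Invariants checked: times increase strictly rootward (every node's tau is
#' below its parent's, with leaves at time 0); internal-node taus are
#' positive; the two nodes of a hybrid pair share one time; all branch
#' population sizes theta are assigned and positive; all introgression
#' probabilities phi are assigned and lie in \eqn{[0, 1]}.
#'
#' @param model an [MSciModel-class].
#' @return character vector of violation messages (length 0 when valid).
#' @export
validateModel <- function(model) {
  nd <- model@nodes
  v <- character()
  idx <- match(nd$parent, nd$name)
  tau <- ifelse(is.na(nd$tau) & nd$type == "leaf", 0, nd$tau)
  for (i in seq_len(nrow(nd))) {
    if (nd$type[i] != "leaf" && (is.na(nd$tau[i]) || nd$tau[i] <= 0))
      v <- c(v, paste0("tau of internal node ", nd$name[i],
                       " must be assigned and positive"))
    if (nd$type[i] == "leaf" && !isTRUE(all.equal(tau[i], 0)))
      v <- c(v, paste0("leaf ", nd$name[i], " must be at time 0"))
    if (!is.na(idx[i]) && !is.na(tau[i]) && !is.na(nd$tau[idx[i]]) &&
        tau[i] >= nd$tau[idx[i]])
      v <- c(v, paste0("tau of node ", nd$name[i],
                       " is not below its parent ", nd$parent[i]))
    if (is.na(nd$theta[i]) || nd$theta[i] <= 0)
      v <- c(v, paste0("theta of branch ", nd$name[i],
                       " must be assigned and positive"))
    if (nd$type[i] == "hybrid" &&
        (is.na(nd$phi[i]) || nd$phi[i] < 0 || nd$phi[i] > 1))
      v <- c(v, paste0("phi of hybrid node ", nd$name[i],
                       " must be assigned and in [0, 1]"))
    if (!is.na(nd$partner[i])) {
      j <- match(nd$partner[i], nd$name)
      if (!is.na(nd$tau[i]) && !is.na(nd$tau[j]) && nd$tau[i] != nd$tau[j] &&
          nd$name[i] < nd$name[j])
        v <- c(v, paste0("paired nodes ", nd$name[i], " and ", nd$name[j],
                         " must share one time"))
    }
  }
  v
}

#' Count the parameters of an MSci model
#'
#' Every branch of the MSci graph (including both parental branches above a
#' hybrid pair and the root stem) carries a population size theta; every
#' speciation node carries a time tau and every hybrid pair one shared tau;
#' every hybrid (recipient) node carries an introgression probability phi.
#'
#' @param model an [MSciModel-class].
#' @return a list with elements \code{n_tau}, \code{n_theta}, \code{n_phi}
#'   and \code{total}.
#' @export
countParameters <- function(model) {
  nd <- model@nodes
  nPairs <- sum(nd$bidirectional) / 2L + sum(nd$type == "donor")
  n <- list(n_tau = sum(nd$type == "speciation") + as.integer(nPairs),
            n_theta = nrow(nd),
            n_phi = sum(nd$type == "hybrid"))
  n$total <- n$n_tau + n$n_theta + n$n_phi
  n
}

## representative of each node on the condensed graph, in which every BDI
## pair is merged into a single node
.condensedRep <- function(nd) {
  rep <- nd$name
  bdi <- which(nd$bidirectional)
  for (i in bdi) {
    pr <- sort(c(nd$name[i], nd$partner[i]))
    rep[i] <- paste(pr, collapse = "+")
  }
  names(rep) <- nd$name
  rep
}

#' Classify a BDI event as sister or nonsister
#'
#' Classification works on the condensed graph in which every BDI node pair
#' is merged into a single node: an event is a sister event exactly when the
#' condensed parents of its two nodes are one node.  Sister events create
#' within-model (label-switching) unidentifiability; nonsister events create
#' cross-model unidentifiability.
#'
#' @param model an [MSciModel-class].
#' @param event a [BDIEvent-class] detected in \code{model}.
#' @return \code{"sister"} or \code{"nonsister"}.
#' @export
classifyBdi <- function(model, event) {
  nd <- model@nodes
  rep <- .condensedRep(nd)
  pX <- rep[nd$parent[match(event@nodeX, nd$name)]]
  pY <- rep[nd$parent[match(event@nodeY, nd$name)]]
  if (identical(unname(pX), unname(pY))) "sister" else "nonsister"
}

#' Detect bidirectional-introgression events
#'
#' Returns one [BDIEvent-class] per hybrid pair whose two horizontal links
#' point at each other (bidirectional).  Unidirectional hybrid nodes are not
#' BDI events; they are listed by [udiNodes()].  Events are ordered by event
#' time (youngest first), ties broken by node name.
#'
#' @param model an [MSciModel-class].
#' @return list of [BDIEvent-class] objects.
#' @export
detectBdiEvents <- function(model) {
  nd <- model@nodes
  bdi <- which(nd$bidirectional)
  if (!length(bdi)) return(list())
  seen <- character()
  events <- list()
  for (i in bdi) {
    key <- paste(sort(c(nd$name[i], nd$partner[i])), collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    j <- match(nd$partner[i], nd$name)
    first <- min(i, j)          # declaration order fixes (X, Y)
    second <- if (first == i) j else i
    ev <- new("BDIEvent",
              nodeX = nd$name[first], nodeY = nd$name[second],
              tau = nd$tau[first],
              params = c(paste0("phi_", nd$name[c(first, second)]),
                         paste0("theta_", nd$name[c(first, second)])),
              sister = NA)
    ev@sister <- classifyBdi(model, ev) == "sister"
    events[[length(events) + 1L]] <- ev
  }
  ord <- order(vapply(events, function(e) e@tau, 0),
               vapply(events, function(e) e@nodeX, ""))
  events[ord]
}

#' Unidirectional hybridization nodes of a model
#'
#' @param model an [MSciModel-class].
#' @return data.frame with columns \code{hybrid}, \code{donor}, \code{tau},
#'   \code{phi} (one row per UDI event).
#' @export
udiNodes <- function(model) {
  nd <- model@nodes
  i <- which(nd$type == "hybrid" & !nd$bidirectional)
  data.frame(hybrid = nd$name[i], donor = nd$partner[i],
             tau = nd$tau[i], phi = nd$phi[i], stringsAsFactors = FALSE)
}

#' Detect a stacked double-BDI pair
#'
#' Two BDI events are stacked when the parental branches of the lower pair
#' are exactly the two child branches of the upper pair (two successive
#' exchanges between the same two lineages).  Stacked pairs are handled with
#' the four-tower transform set of [doubleBdiMappings()] instead of two
#' independent single-event mirrors.
#'
#' @param model an [MSciModel-class].
#' @param lower,upper [BDIEvent-class] objects, \code{lower} the younger.
#' @return logical.
#' @export
isStackedPair <- function(model, lower, upper) {
  nd <- model@nodes
  pars <- nd$parent[match(c(lower@nodeX, lower@nodeY), nd$name)]
  setequal(pars, c(upper@nodeX, upper@nodeY)) && lower@tau < upper@tau
}

#' Node table of an MSci model
#' @param model an [MSciModel-class].
#' @return the model's \code{data.frame} of nodes.
#' @export
modelNodes <- function(model) model@nodes

#' Species (leaf) names of an MSci model
#' @param model an [MSciModel-class].
#' @return character vector.
#' @export
speciesNames <- function(model) {
  nd <- model@nodes
  nd$name[nd$type == "leaf"]
}

#' Named parameter vector of an MSci model
#'
#' Parameters are named \code{tau_<node>} (one per speciation node, one per
#' hybrid pair named after its first node), \code{theta_<branch>} and
#' \code{phi_<hybrid node>} — the naming used by sample tables and tower
#' mappings throughout the package.
#'
#' @param model an [MSciModel-class].
#' @return named numeric vector.
#' @export
modelParams <- function(model) {
  nd <- model@nodes
  out <- numeric()
  sp <- nd$name[nd$type == "speciation"]
  out[paste0("tau_", sp)] <- nd$tau[match(sp, nd$name)]
  hy <- which(nd$type %in% c("hybrid", "donor"))
  seen <- character()
  for (i in hy) {
    key <- paste(sort(c(nd$name[i], nd$partner[i])), collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    j <- match(nd$partner[i], nd$name)
    first <- nd$name[min(i, j)]
    out[paste0("tau_", first)] <- nd$tau[match(first, nd$name)]
  }
  out[paste0("theta_", nd$name)] <- nd$theta
  hyb <- nd$name[nd$type == "hybrid"]
  out[paste0("phi_", hyb)] <- nd$phi[match(hyb, nd$name)]
  out
}

#' @describeIn MSciModel-class compact display of nodes and parameter counts
#' @param object an \code{MSciModel}.
#' @export
setMethod("show", "MSciModel", function(object) {
  nd <- object@nodes
  cnt <- countParameters(object)
  ev <- detectBdiEvents(object)
  cat("MSciModel:", sum(nd$type == "leaf"), "species,",
      sum(nd$bidirectional) / 2, "BDI event(s),",
      sum(nd$type == "donor"), "UDI event(s)\n")
  cat("  parameters:", cnt$total, sprintf("(%d theta, %d tau, %d phi)\n",
      cnt$n_theta, cnt$n_tau, cnt$n_phi))
  for (e in ev)
    cat(sprintf("  BDI %s-%s at tau=%s [%s]\n", e@nodeX, e@nodeY,
                fmtNum(e@tau), if (e@sister) "sister" else "nonsister"))
  invisible(object)
})

#' @describeIn BDIEvent-class display the event and its governed parameters
#' @param object a \code{BDIEvent}.
#' @export
setMethod("show", "BDIEvent", function(object) {
  cat(sprintf("BDIEvent %s-%s at tau=%s (%s): %s\n",
              object@nodeX, object@nodeY, fmtNum(object@tau),
              if (object@sister) "sister" else "nonsister",
              paste(object@params, collapse = ", ")))
  invisible(object)
})
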