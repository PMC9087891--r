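#' @import methods
NULL

#' MSci model with introgression events
#'
#' An MSci model is a rooted, ultrametric species tree augmented with
#' hybridization nodes inserted on its branches.  Hybridization nodes come in
#' pairs: a bidirectional-introgression (BDI) pair places one hybrid node on
#' each of two contemporaneous branches, with the horizontal edges pointing at
#' each other; a unidirectional (UDI) event places a hybrid (recipient) node
#' on one branch and a plain donor node on another.
#'
#' The model is stored as a node table.  Each node owns the branch connecting
#' it to its parent (the root node owns the root stem), so every node carries
#' a population size \eqn{\theta} for that branch.  Internal nodes carry a
#' time \eqn{\tau}; the two nodes of a hybrid pair share one time.  Hybrid
#' (recipient) nodes carry an introgression probability \eqn{\phi}: the
#' probability that a lineage tracing backwards through the node takes the
#' horizontal (cross-population) parent path; with probability \eqn{1-\phi}
#' it continues up its own branch.  Times and population sizes are measured
#' in expected substitutions per site.
#'
#' @slot nodes a \code{data.frame} with one row per node and columns
#'   \code{name}, \code{type} (\code{"leaf"}, \code{"speciation"},
#'   \code{"hybrid"}, \code{"donor"}), \code{parent} (name, \code{NA} for the
#'   root), \code{partner} (paired node of a hybrid/donor, else \code{NA}),
#'   \code{bidirectional} (logical, \code{TRUE} for BDI hybrid nodes),
#'   \code{tau}, \code{theta}, \code{phi}.
#'
#' @seealso [parseModel()], [countParameters()], [detectBdiEvents()],
#'   [enumerateTowers()]
#' @export
setClass("MSciModel", representation(nodes = "data.frame"))

#' A detected bidirectional-introgression event
#'
#' @slot nodeX,nodeY names of the two paired hybrid nodes (in declaration
#'   order).
#' @slot tau the shared event time.
#' @slot params the four governed parameter names, in the order
#'   \code{phi_X}, \code{phi_Y}, \code{theta_X}, \code{theta_Y}, where
#'   \code{theta_} names refer to the parental branches directly above the
#'   two hybrid nodes.
#' @slot sister logical; \code{TRUE} when the two nodes are sisters on the
#'   condensed graph (each hybrid pair merged into a single node), which is
#'   the within-model (label-switching) case.
#' @export
setClass("BDIEvent", representation(
  nodeX = "character", nodeY = "character", tau = "numeric",
  params = "character", sister = "logical"
))

#' One unidentifiable-tower parameter mapping
#'
#' A mapping sends a named parameter vector to an equivalent point in an
#' unidentifiable tower.  Each affected parameter receives the value of a
#' source parameter, optionally complemented (\eqn{x \mapsto 1-x}, applied to
#' introgression probabilities only); parameters not listed are copied
#' unchanged.  Within-model mappings are involutions; compositions of
#' event-wise involutions are closed under composition.
#'
#' @slot target,source character vectors of parameter names: slot
#'   \code{target[i]} receives (a function of) the value of \code{source[i]}.
#' @slot complement logical vector; \code{TRUE} entries apply \eqn{1-x}.
#' @slot label short identifier (e.g. tower binary code).
#' @slot topology \code{"same-model"} for within-model mappings, otherwise a
#'   tag describing the mirrored topology of the target model variant.
#' @slot events names of the BDI events the mapping is composed from.
#' @seealso [applyMapping()], [singleBdiMapping()], [doubleBdiMappings()]
#' @export
setClass("TowerMapping", representation(
  target = "character", source = "character", complement = "logical",
  label = "character", topology = "character", events = "character"
))

#' The full set of unidentifiable models and towers implied by a model
#'
#' For a model with \eqn{m} sister BDI events and \eqn{n} nonsister BDI
#' events there are \eqn{2^n} unidentifiable model variants, each with
#' \eqn{2^m} within-model towers.
#'
#' @slot variants list; each element is a list with elements \code{tag}
#'   (topology tag), \code{flipped} (names of nonsister events mirrored in
#'   this variant) and \code{mappings} (list of [TowerMapping-class] objects,
#'   ordered by tower binary code with the youngest event as the
#'   least-significant bit).
#' @slot m,n integer counts of sister and nonsister BDI events.
#' @export
setClass("TowerSet", representation(
  variants = "list", m = "integer", n = "integer"
))

#' Result of one relabeling pass over an MCMC sample table
#'
#' @slot samples the processed sample table (each row is the image of the
#'   input row under the mapping selected by its final label).
#' @slot labels integer vector of per-row transform indicators
#'   \eqn{z_t \in \{0, \dots, T-1\}}.
#' @slot iterations number of full iterations performed.
#' @slot objective per-iteration objective values: the sum of squared
#'   distances for CoG algorithms (nonincreasing for CoG0) or the
#'   beta-gamma log likelihood (nondecreasing).
#' @slot algorithm one of \code{"cog0"}, \code{"cogn"}, \code{"betagamma"}
#'   (possibly with a density-family suffix).
#' @slot mappings the transform list used (identity first).
#' @export
setClass("RelabelResult", representation(
  samples = "data.frame", labels = "integer", iterations = "integer",
  objective = "numeric", algorithm = "character", mappings = "list"
))

setValidity("MSciModel", function(object) {
  nd <- object@nodes
  need <- c("name", "type", "parent", "partner", "bidirectional",
            "tau", "theta", "phi")
  if (!all(need %in% names(nd)))
    return(paste("nodes table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$name)) return("duplicated node names")
  if (sum(is.na(nd$parent)) != 1L) return("model must have exactly one root")
  TRUE
})

setValidity("TowerMapping", function(object) {
  n <- length(object@target)
  if (length(object@source) != n || length(object@complement) != n)
    return("target, source and complement must have equal length")
  if (anyDuplicated(object@target)) return("duplicated target parameters")
  TRUE
})

setValidity("RelabelResult", function(object) {
  if (length(object@labels) != nrow(object@samples))
    return("labels length must equal the number of sample rows")
  TRUE
})
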