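## Backwards-in-time coalescent with episodic introgression.
##
## Populations are the branches of the MSci graph, keyed by their daughter
## node.  Between events, lineages sharing a population coalesce at rate
## k(k-1)/theta (pairwise rate 2/theta).  At a hybridization-pair time each
## lineage in a child population independently takes the horizontal parent
## path with the node's phi; at a speciation time the daughter populations
## merge into the parental one.  All surviving lineages coalesce in the
## root population.

## Event schedule: one entry per speciation node and one per hybrid pair,
## ascending in time.
.eventSchedule <- function(nd) {
  sched <- list()
  childOf <- function(name) nd$name[!is.na(nd$parent) & nd$parent == name]
  for (i in which(nd$type == "speciation")) {
    sched[[length(sched) + 1L]] <- list(
      kind = "speciation", tau = nd$tau[i], node = nd$name[i],
      children = childOf(nd$name[i]))
  }
  seen <- character()
  for (i in which(nd$type %in% c("hybrid", "donor"))) {
    key <- paste(sort(c(nd$name[i], nd$partner[i])), collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    j <- match(nd$partner[i], nd$name)
    hset <- c(i, j)[nd$type[c(i, j)] == "hybrid"]
    sched[[length(sched) + 1L]] <- list(
      kind = "hybrid", tau = nd$tau[i],
      nodes = nd$name[c(i, j)],
      children = vapply(nd$name[c(i, j)],
                        function(nm) childOf(nm)[1], ""),
      phi = nd$phi[c(i, j)],
      ## destination of the horizontal path: the partner's own branch
      horiz = nd$name[c(j, i)])
  }
  sched[order(vapply(sched, `[[`, 0, "tau"))]
}

## Coalesce lineages within populations over (t0, t1]; pops/times/active are
## vectors over lineage slots; merges records rows (child1, child2, newid, t).
.coalesceInterval <- function(state, theta, t0, t1) {
  for (pop in unique(state$pop[state$active])) {
    repeat {
      idx <- which(state$active & state$pop == pop)
      k <- length(idx)
      if (k < 2L) break
      rate <- k * (k - 1) / theta[[pop]]
      tw <- stats::rexp(1L, rate)
      if (!is.finite(t1) || t0 + tw < t1) {
        t0p <- t0 + tw
        pair <- sample(idx, 2L)
        newid <- state$nextid
        state$nextid <- newid + 1L
        state$merges[[length(state$merges) + 1L]] <-
          c(pair[1], pair[2], newid, t0p)
        state$active[pair] <- FALSE
        state$pop <- c(state$pop, pop)
        state$active <- c(state$active, TRUE)
        state$ids <- c(state$ids, newid)
        t0 <- t0p
      } else break
    }
  }
  state
}

.simulateOneGenetree <- function(nd, sched, theta, tips, tipPop) {
  n <- length(tips)
  state <- list(pop = tipPop, active = rep(TRUE, n), ids = seq_len(n),
                nextid = n + 1L, merges = list(),
                paths = list())
  t0 <- 0
  for (ev in sched) {
    state <- .coalesceInterval(state, theta, t0, ev$tau)
    t0 <- ev$tau
    if (ev$kind == "speciation") {
      state$pop[state$active & state$pop %in% ev$children] <- ev$node
    } else {
      ## process both hybrid-pair nodes on the pre-event populations
      moveTo <- character(0)
      movers <- integer(0)
      for (h in seq_along(ev$nodes)) {
        idx <- which(state$active & state$pop == ev$children[h])
        if (!length(idx)) next
        phi <- ev$phi[h]
        horizontal <- if (is.na(phi)) rep(FALSE, length(idx)) else
          stats::runif(length(idx)) < phi
        dest <- ifelse(horizontal, ev$horiz[h], ev$nodes[h])
        movers <- c(movers, idx)
        moveTo <- c(moveTo, dest)
        if (!is.na(phi))
          state$paths[[length(state$paths) + 1L]] <-
            list(lineage = state$ids[idx], node = ev$nodes[h],
                 horizontal = horizontal, time = ev$tau)
      }
      state$pop[movers] <- moveTo
    }
  }
  state <- .coalesceInterval(state, theta, t0, Inf)
  .buildPhylo(state, tips)
}

.buildPhylo <- function(state, tips) {
  n <- length(tips)
  merges <- do.call(rbind, state$merges)
  stopifnot(nrow(merges) == n - 1L)
  ## ape numbering: tips 1..n, root n+1, internals follow; merge ids n+1..2n-1
  ## map merge ids (created youngest first) to ape internal numbers: the
  ## last-created internal node is the root
  apeNum <- integer(2L * n - 1L)
  apeNum[seq_len(n)] <- seq_len(n)
  ord <- order(-merges[, 4])          # oldest (root) first
  inum <- n + 1L
  for (r in ord) {
    apeNum[merges[r, 3]] <- inum
    inum <- inum + 1L
  }
  nodeTime <- numeric(2L * n - 1L)
  nodeTime[apeNum[merges[, 3]]] <- merges[, 4]
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  edgeLen <- numeric(2L * (n - 1L))
  e <- 1L
  for (r in seq_len(nrow(merges))) {
    par <- apeNum[merges[r, 3]]
    for (child in merges[r, 1:2]) {
      edge[e, ] <- c(par, apeNum[child])
      edgeLen[e] <- merges[r, 4] - nodeTime[apeNum[child]]
      e <- e + 1L
    }
  }
  tr <- structure(list(edge = edge, edge.length = edgeLen,
                       tip.label = tips, Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "nodeTimes") <- nodeTime
  if (length(state$paths)) {
    p <- state$paths
    attr(tr, "paths") <- list(
      lineage = unlist(lapply(p, `[[`, "lineage"), use.names = FALSE),
      node = rep(vapply(p, `[[`, "", "node"),
                 lengths(lapply(p, `[[`, "lineage"))),
      path = ifelse(unlist(lapply(p, `[[`, "horizontal"),
                           use.names = FALSE), "horizontal", "vertical"),
      time = rep(vapply(p, `[[`, 0, "time"),
                 lengths(lapply(p, `[[`, "lineage"))))
  }
  tr
}

#' Simulate gene trees under an MSci model
#'
#' Simulates per-locus genealogies by the backwards-in-time coalescent with
#' episodic introgression: within each population of \eqn{k} lineages and
#' size \eqn{\theta}, coalescent waiting times are exponential with rate
#' \eqn{k(k-1)/\theta}; at a hybridization-pair time each lineage in a child
#' population independently takes the horizontal parent path with the
#' hybrid node's \eqn{\phi}; daughter populations merge at speciation times;
#' all surviving lineages coalesce in the root population.  Times are in
#' expected substitutions per site throughout.
#'
#' Each locus uses its own RNG stream derived from \code{(seed, locus)}, so
#' changing \code{nloci} does not perturb earlier loci.
#'
#' @param model a valid [MSciModel-class].
#' @param nseq named integer vector of per-species sample sizes (species
#'   omitted or 0 contribute no lineages); at least one lineage overall and
#'   two for a nontrivial genealogy.
#' @param nloci number of independent loci.
#' @param seed master seed.
#' @return list of \code{phylo} gene trees (class \code{multiPhylo}); each
#'   tree carries a \code{"nodeTimes"} attribute (coalescent times, tips at
#'   0) and, when introgression occurred on its history, a \code{"paths"}
#'   attribute: parallel vectors \code{lineage}, \code{node}, \code{path}
#'   (\code{"horizontal"}/\code{"vertical"}), \code{time} recording the
#'   parental path taken by each lineage at each hybridization node passed.
#' @seealso [coalescentTimes()], [pairwiseCoalDensity()]
#' @export
simulateGeneTrees <- function(model, nseq, nloci, seed = 1L) {
  nd <- model@nodes
  sp <- speciesNames(model)
  bad <- setdiff(names(nseq), sp)
  if (length(bad))
    stop("unknown species in nseq: ", paste(bad, collapse = ", "))
  nseq <- nseq[nseq > 0]
  if (sum(nseq) < 2L)
    stop("need at least two sampled sequences overall")
  tips <- unlist(lapply(names(nseq), function(s)
    paste0(s, "_", seq_len(nseq[[s]]))), use.names = FALSE)
  tipPop <- rep(names(nseq), unlist(nseq))
  sched <- .eventSchedule(nd)
  theta <- stats::setNames(as.list(nd$theta), nd$name)

  trees <- vector("list", nloci)
  base <- as.double(seed %% 2147483647L)
  for (locus in seq_len(nloci)) {
    set.seed(as.integer((base * 48271 + locus * 16807) %% 2147483647))
    trees[[locus]] <- .simulateOneGenetree(nd, sched, theta, tips, tipPop)
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Coalescent times of simulated gene trees
#'
#' @param trees result of [simulateGeneTrees()], or a single such tree.
#' @return for one tree, its internal-node times (tips at 0); for a list,
#'   the vector of root (deepest-coalescence) times across loci.
#' @export
coalescentTimes <- function(trees) {
  one <- function(tr) {
    nt <- attr(tr, "nodeTimes")
    nt[-seq_along(tr$tip.label)]
  }
  if (inherits(trees, "phylo")) return(one(trees))
  vapply(unclass(trees), function(tr) max(one(tr)), 0)
}

#' Analytic pairwise coalescent density for the two-species BDI model
#'
#' For one sequence from each of the two species of the basic two-species
#' BDI model, the density of the coalescent time \eqn{t} is piecewise: zero
#' before the introgression time \eqn{\tau_X} (the lineages share no
#' population); on \eqn{[\tau_X, \tau_R)} a two-term mixture over the two
#' histories that put both lineages in one parental population — both in
#' the X-side branch with weight \eqn{(1-\phi_X)\phi_Y} and rate
#' \eqn{2/\theta_X}, or both in the Y-side branch with weight
#' \eqn{\phi_X(1-\phi_Y)} and rate \eqn{2/\theta_Y}; beyond \eqn{\tau_R}
#' the surviving probability mass times the root-population exponential.
#' The density is invariant under the mirror mapping of
#' [singleBdiMapping()], which exchanges the two mixture terms exactly.
#'
#' @param model a two-species [MSciModel-class] with exactly one BDI event
#'   (the basic BDI shape).
#' @param t vector of times (expected substitutions per site).
#' @return density values at \code{t}.
#' @export
pairwiseCoalDensity <- function(model, t) {
  nd <- model@nodes
  ev <- detectBdiEvents(model)
  if (length(speciesNames(model)) != 2L || length(ev) != 1L ||
      sum(nd$type == "speciation") != 1L)
    stop("model must be the basic two-species single-BDI shape")
  e <- ev[[1]]
  phiX <- nd$phi[match(e@nodeX, nd$name)]
  phiY <- nd$phi[match(e@nodeY, nd$name)]
  thX <- nd$theta[match(e@nodeX, nd$name)]
  thY <- nd$theta[match(e@nodeY, nd$name)]
  root <- nd$name[is.na(nd$parent)]
  thR <- nd$theta[match(root, nd$name)]
  tauX <- e@tau
  tauR <- nd$tau[match(root, nd$name)]

  wX <- (1 - phiX) * phiY             # both lineages take the X-side branch
  wY <- phiX * (1 - phiY)             # both take the Y-side branch
  mid <- function(tt)
    wX * (2 / thX) * exp(-2 * (tt - tauX) / thX) +
    wY * (2 / thY) * exp(-2 * (tt - tauX) / thY)
  surv <- 1 - wX * (1 - exp(-2 * (tauR - tauX) / thX)) -
    wY * (1 - exp(-2 * (tauR - tauX) / thY))
  out <- numeric(length(t))
  inMid <- t >= tauX & t < tauR
  out[inMid] <- mid(t[inMid])
  inRoot <- t >= tauR
  out[inRoot] <- surv * (2 / thR) * exp(-2 * (t[inRoot] - tauR) / thR)
  out
}
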