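## Line-oriented MSci model-spec format.
##
##   tree ((A,B)R;)
##   bdi X=A@0.00125 Y=B@0.00125
##   udi H=C@0.001 S=D@0.001
##   tau R=0.005
##   theta A=0.005 B=0.02 R=0.005 X=0.005 Y=0.02
##   phi X=0.1 Y=0.2
##
## The `tree` line gives the backbone species tree in Newick with labelled
## internal nodes.  A `bdi` line introduces a bidirectional hybrid pair: node
## X on the branch to A and node Y on the branch to B, both at the stated
## time.  A `udi` line introduces a unidirectional event: hybrid (recipient)
## node H on the branch to C and donor node S on the branch to D.  `tau`,
## `theta` and `phi` lines assign parameters by node name; theta is per
## branch (named by its daughter node, the root name denoting the root stem).

fmtNum <- function(x) trimws(formatC(x, format = "g", digits = 15))

.emptyNodes <- function() {
  data.frame(name = character(), type = character(), parent = character(),
             partner = character(), bidirectional = logical(),
             tau = numeric(), theta = numeric(), phi = numeric(),
             stringsAsFactors = FALSE)
}

.parseAssignments <- function(rest, what, line) {
  toks <- strsplit(trimws(rest), "[[:space:]]+")[[1]]
  out <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^([^=@]+)=([^=@]+)(@([^=@]+))?$", tk))[[1]]
    if (length(m) == 0L)
      stop("syntax error in '", what, "' line: ", line, call. = FALSE)
    list(name = m[2], value = m[3], at = if (nzchar(m[5])) m[5] else NA_character_)
  })
  out
}

.num <- function(s, what) {
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) stop("not a number in ", what, ": '", s, "'", call. = FALSE)
  x
}

## Insert a hybrid/donor node on the branch above `ref` at time `t`,
## climbing through previously inserted nodes so stacked events nest by time.
.insertNode <- function(nd, newname, ref, t, type) {
  if (newname %in% nd$name)
    stop("duplicated node name: ", newname, call. = FALSE)
  if (!(ref %in% nd$name))
    stop("unknown node name: ", ref, call. = FALSE)
  u <- ref
  repeat {
    p <- nd$parent[nd$name == u]
    if (is.na(p))
      stop("cannot place node ", newname, " above the root", call. = FALSE)
    tu <- nd$tau[nd$name == u]
    tp <- nd$tau[nd$name == p]
    if (is.na(tu)) tu <- 0
    if (is.na(tp))
      stop("node ", p, " needs a tau before events can be placed near it",
           call. = FALSE)
    if (t <= tu)
      stop("event time ", fmtNum(t), " is not above node ", u, call. = FALSE)
    if (t < tp) break
    u <- p
  }
  p <- nd$parent[nd$name == u]
  nd$parent[nd$name == u] <- newname
  rbind(nd, data.frame(name = newname, type = type, parent = p,
                       partner = NA_character_, bidirectional = FALSE,
                       tau = t, theta = NA_real_, phi = NA_real_,
                       stringsAsFactors = FALSE))
}

.backboneFromNewick <- function(newick) {
  tr <- ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse the tree line", call. = FALSE)
  nint <- tr$Nnode
  ntip <- length(tr$tip.label)
  labs <- c(tr$tip.label, tr$node.label)
  if (is.null(tr$node.label) || length(tr$node.label) != nint ||
      any(!nzchar(tr$node.label)))
    stop("every internal node of the tree must be labelled", call. = FALSE)
  if (anyDuplicated(labs)) stop("duplicated node labels in tree", call. = FALSE)
  parent <- rep(NA_character_, ntip + nint)
  for (i in seq_len(nrow(tr$edge)))
    parent[tr$edge[i, 2]] <- labs[tr$edge[i, 1]]
  data.frame(name = labs,
             type = rep(c("leaf", "speciation"), c(ntip, nint)),
             parent = parent,
             partner = NA_character_, bidirectional = FALSE,
             tau = c(rep(0, ntip), rep(NA_real_, nint)),
             theta = NA_real_, phi = NA_real_,
             stringsAsFactors = FALSE)
}

#' Parse an MSci model description
#'
#' Reads the line-oriented model-spec format (see the package vignette) into
#' an [MSciModel-class] object.  With \code{strict = TRUE} (the default) the
#' parsed model is passed through [validateModel()] and any violation is an
#' error; with \code{strict = FALSE} structurally parseable but invalid
#' models are returned so that [validateModel()] can report all violations.
#'
#' @param text the model description, as a single string or a character
#'   vector of lines.
#' @param strict stop on validation violations?
#' @return an [MSciModel-class].
#' @seealso [readMSciModel()], [writeModel()], [validateModel()]
#' @examples
#' m <- parseModel(c(
#'   "tree ((A,B)R;)",
#'   "bdi X=A@0.00125 Y=B@0.00125",
#'   "tau R=0.005",
#'   "theta A=0.005 B=0.02 R=0.005 X=0.005 Y=0.02",
#'   "phi X=0.1 Y=0.2"))
#' countParameters(m)$total  # 9
#' @export
parseModel <- function(text, strict = TRUE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kw <- sub("\\s.*$", "", lines)
  rest <- sub("^\\S+\\s*", "", lines)

  bad <- setdiff(unique(kw), c("tree", "bdi", "udi", "tau", "theta", "phi"))
  if (length(bad))
    stop("unknown directive(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (sum(kw == "tree") != 1L)
    stop("the model must contain exactly one 'tree' line", call. = FALSE)

  newick <- rest[kw == "tree"]
  if (grepl("^\\(.*;\\)$", newick))
    newick <- substr(newick, 2L, nchar(newick) - 1L)
  if (!grepl(";\\s*$", newick)) newick <- paste0(newick, ";")
  nd <- .backboneFromNewick(newick)

  ## backbone taus must be known before hybrid nodes can be placed by time
  for (i in which(kw == "tau")) {
    for (a in .parseAssignments(rest[i], "tau", lines[i])) {
      if (!(a$name %in% nd$name))
        stop("unknown node in tau line: ", a$name, call. = FALSE)
      nd$tau[nd$name == a$name] <- .num(a$value, "tau")
    }
  }

  events <- list()
  for (i in which(kw %in% c("bdi", "udi"))) {
    as <- .parseAssignments(rest[i], kw[i], lines[i])
    if (length(as) != 2L || any(vapply(as, function(a) is.na(a$at), TRUE)))
      stop("'", kw[i], "' lines need two name=ref@time entries: ", lines[i],
           call. = FALSE)
    events[[length(events) + 1L]] <- list(
      kind = kw[i],
      names = vapply(as, `[[`, "", "name"),
      refs = vapply(as, `[[`, "", "value"),
      times = vapply(as, function(a) .num(a$at, kw[i]), 0))
  }
  if (length(events)) {
    ord <- order(vapply(events, function(e) min(e$times), 0))
    for (e in events[ord]) {
      types <- if (e$kind == "bdi") c("hybrid", "hybrid") else c("hybrid", "donor")
      for (j in 1:2)
        nd <- .insertNode(nd, e$names[j], e$refs[j], e$times[j], types[j])
      nd$partner[nd$name == e$names[1]] <- e$names[2]
      nd$partner[nd$name == e$names[2]] <- e$names[1]
      if (e$kind == "bdi")
        nd$bidirectional[nd$name %in% e$names] <- TRUE
    }
  }

  for (i in which(kw == "theta")) {
    for (a in .parseAssignments(rest[i], "theta", lines[i])) {
      if (!(a$name %in% nd$name))
        stop("unknown node in theta line: ", a$name, call. = FALSE)
      nd$theta[nd$name == a$name] <- .num(a$value, "theta")
    }
  }
  for (i in which(kw == "phi")) {
    for (a in .parseAssignments(rest[i], "phi", lines[i])) {
      if (!(nd$type[match(a$name, nd$name)] %in% "hybrid"))
        stop("phi assigned to non-hybrid node: ", a$name, call. = FALSE)
      nd$phi[nd$name == a$name] <- .num(a$value, "phi")
    }
  }

  model <- new("MSciModel", nodes = nd)
  if (strict) {
    v <- validateModel(model)
    if (length(v))
      stop("invalid model:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' Read an MSci model from a file
#'
#' @param path path to a model-spec file.
#' @inheritParams parseModel
#' @return an [MSciModel-class].
#' @export
readMSciModel <- function(path, strict = TRUE)
  parseModel(readLines(path, warn = FALSE), strict = strict)

.backboneChildren <- function(nd, name) {
  ## children in the condensed backbone: descend through hybrid/donor nodes
  kids <- nd$name[!is.na(nd$parent) & nd$parent == name]
  out <- character()
  for (k in kids) {
    while (nd$type[match(k, nd$name)] %in% c("hybrid", "donor"))
      k <- nd$name[!is.na(nd$parent) & nd$parent == k]
    out <- c(out, k)
  }
  sort(out)
}

.newickFrom <- function(nd, name) {
  kids <- .backboneChildren(nd, name)
  if (length(kids) == 0L) return(name)
  paste0("(", paste(vapply(kids, function(k) .newickFrom(nd, k), ""),
                    collapse = ","), ")", name)
}

#' Write an MSci model in the model-spec format
#'
#' Emits the canonical dialect read by [parseModel()]: children and
#' parameter assignments are ordered alphabetically and event lines by event
#' time, so that writing is deterministic and \code{parseModel(writeModel(m))}
#' reproduces \code{writeModel(m)} bit-exactly.
#'
#' @param model an [MSciModel-class].
#' @param path optional output file; when \code{NULL} the text is returned.
#' @return the model text, invisibly when written to \code{path}.
#' @export
writeModel <- function(model, path = NULL) {
  nd <- model@nodes
  root <- nd$name[is.na(nd$parent)]
  out <- paste0("tree (", .newickFrom(nd, root), ";)")

  childOf <- function(name) nd$name[!is.na(nd$parent) & nd$parent == name]
  hy <- nd[nd$type %in% c("hybrid", "donor"), , drop = FALSE]
  if (nrow(hy)) {
    pairs <- unique(t(apply(cbind(hy$name, hy$partner), 1L, sort)))
    first <- vapply(seq_len(nrow(pairs)), function(i) {
      ## keep declaration order: hybrid (recipient) of a UDI pair first,
      ## else earliest row in the node table
      a <- pairs[i, 1]; b <- pairs[i, 2]
      ta <- nd$type[match(a, nd$name)]; tb <- nd$type[match(b, nd$name)]
      if (ta == "donor") b
      else if (tb == "donor") a
      else if (match(a, nd$name) < match(b, nd$name)) a else b
    }, "")
    second <- ifelse(pairs[, 1] == first, pairs[, 2], pairs[, 1])
    tm <- nd$tau[match(first, nd$name)]
    ord <- order(tm, first)
    for (i in ord) {
      kind <- if (nd$bidirectional[match(first[i], nd$name)]) "bdi" else "udi"
      out <- c(out, paste0(
        kind, " ",
        first[i], "=", childOf(first[i]), "@",
        fmtNum(nd$tau[match(first[i], nd$name)]), " ",
        second[i], "=", childOf(second[i]), "@",
        fmtNum(nd$tau[match(second[i], nd$name)])))
    }
  }

  sp <- sort(nd$name[nd$type == "speciation"])
  out <- c(out, paste("tau", paste0(
    sp, "=", fmtNum(nd$tau[match(sp, nd$name)]), collapse = " ")))
  all <- sort(nd$name)
  th <- nd$theta[match(all, nd$name)]
  keep <- !is.na(th)
  out <- c(out, paste("theta", paste0(
    all[keep], "=", fmtNum(th[keep]), collapse = " ")))
  hyb <- sort(nd$name[nd$type == "hybrid"])
  if (length(hyb)) {
    ph <- nd$phi[match(hyb, nd$name)]
    keep <- !is.na(ph)
    if (any(keep))
      out <- c(out, paste("phi", paste0(
        hyb[keep], "=", fmtNum(ph[keep]), collapse = " ")))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}
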