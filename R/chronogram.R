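#' Chronogram: a rooted tree with node ages and per-node annotations
#'
#' A `chronogram` wraps an [ape::phylo] tree together with a per-node
#' annotation table.  Ages are measured backwards from the present, in Ma:
#' extant tips sit at age 0 and branch lengths in a dated tree are age
#' differences between parent and child.  Annotations carry clade support
#' (in `[0, 1]`), highest-density age intervals (`hpd_min`/`hpd_max`) and,
#' for biogeographic analyses, a set of area codes per node.
#'
#' @param phy a rooted `phylo` object with branch lengths.
#' @param data optional data frame with one row per annotated node and
#'   columns `node` (node id in `phy`'s numbering), plus any of `support`,
#'   `hpd_min`, `hpd_max`, `areas` (comma-separated area codes).
#' @return an object of class `chronogram` with elements `phy` and `data`.
#' @export
chronogram <- function(phy, data = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be a 'phylo' object")
  if (is.null(phy$edge.length)) stop("phy must have branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  if (is.null(data)) {
    data <- data.frame(node = integer(), support = numeric(),
                       hpd_min = numeric(), hpd_max = numeric(),
                       areas = character(), extra = character(),
                       stringsAsFactors = FALSE)
  } else {
    data <- as.data.frame(data)
    if (!"node" %in% names(data)) stop("annotation data must have a 'node' column")
    for (f in c("support", "hpd_min", "hpd_max"))
      if (!f %in% names(data)) data[[f]] <- NA_real_
    for (f in c("areas", "extra"))
      if (!f %in% names(data)) data[[f]] <- NA_character_
    if (any(data$node < 1 | data$node > n_nodes))
      stop("annotation node ids out of range")
    if (anyDuplicated(data$node)) stop("duplicated annotation node ids")
    data <- data[, c("node", "support", "hpd_min", "hpd_max", "areas", "extra")]
  }
  structure(list(phy = phy, data = data), class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat("chronogram:", ape::Ntip(x$phy), "tips,", x$phy$Nnode, "internal nodes\n")
  ages <- node_ages(x)
  cat(sprintf("root age %.4f; %d annotated node(s)\n",
              max(ages), nrow(x$data)))
  invisible(x)
}

#' Coerce to chronogram
#' @param x a `phylo` or `chronogram`.
#' @return a `chronogram`.
#' @export
as_chronogram <- function(x) {
  if (inherits(x, "chronogram")) return(x)
  chronogram(x)
}

#' Node ages of a dated tree
#'
#' Ages are computed from branch lengths as (maximum root-to-tip depth)
#' minus the node's own depth, so on an ultrametric tree all tips are at 0.
#'
#' @param x a `chronogram` or rooted `phylo`.
#' @return numeric vector indexed by node id (tips first, ape convention).
#' @export
node_ages <- function(x) {
  phy <- if (inherits(x, "chronogram")) x$phy else x
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_len(ape::Ntip(phy))]) - depth
}

#' Check the dated-tree invariants
#'
#' Verifies that branch lengths are nonnegative, every parent is at least
#' as old as its children, all tips sit at age 0 (ultrametricity) and any
#' HPD interval contains its node's age.  Called at module boundaries so a
#' malformed tree fails early rather than propagating.
#'
#' @param x a `chronogram` or `phylo`.
#' @param tol numeric tolerance on ultrametricity, in age units.
#' @return `x`, invisibly; stops with a message on violation.
#' @export
validate_chronogram <- function(x, tol = 1e-6) {
  chron <- as_chronogram(x)
  phy <- chron$phy
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (any(phy$edge.length < -tol)) stop("negative branch length")
  ages <- node_ages(chron)
  tip_ages <- ages[seq_len(ape::Ntip(phy))]
  if (any(abs(tip_ages) > tol))
    stop("tree is not ultrametric: tip ages deviate from 0 by up to ",
         format(max(abs(tip_ages))))
  parent_age <- ages[phy$edge[, 1]]
  child_age <- ages[phy$edge[, 2]]
  if (any(parent_age < child_age - tol)) stop("parent younger than child")
  d <- chron$data
  if (nrow(d)) {
    has <- !is.na(d$hpd_min) & !is.na(d$hpd_max)
    if (any(has)) {
      a <- ages[d$node[has]]
      if (any(d$hpd_min[has] > a + tol) || any(d$hpd_max[has] < a - tol))
        stop("HPD interval does not contain node age")
      if (any(d$hpd_min[has] > d$hpd_max[has]))
        stop("hpd_min exceeds hpd_max")
    }
  }
  invisible(x)
}

anno_lookup <- function(chron, node) {
  i <- match(node, chron$data$node)
  if (is.na(i)) NULL else chron$data[i, , drop = FALSE]
}

set_anno <- function(chron, node, support = NA_real_, hpd_min = NA_real_,
                     hpd_max = NA_real_, areas = NA_character_,
                     extra = NA_character_) {
  i <- match(node, chron$data$node)
  row <- data.frame(node = node, support = support, hpd_min = hpd_min,
                    hpd_max = hpd_max, areas = areas, extra = extra,
                    stringsAsFactors = FALSE)
  if (is.na(i)) chron$data <- rbind(chron$data, row)
  else chron$data[i, ] <- row
  chron
}

# ---- nested-list view, used by the grafting machinery -----------------------
# Each node is list(label, age, support, hpd = c(lo, hi) | NULL,
#                   areas = character() | NULL, children = list()).

chron_to_nested <- function(chron) {
  chron <- as_chronogram(chron)
  phy <- chron$phy
  ages <- node_ages(chron)
  ntip <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    a <- anno_lookup(chron, node)
    out <- list(
      label = if (node <= ntip) phy$tip.label[node] else
        if (!is.null(phy$node.label)) phy$node.label[node - ntip] else NULL,
      age = ages[node],
      support = if (!is.null(a)) a$support else NA_real_,
      hpd = if (!is.null(a) && !is.na(a$hpd_min)) c(a$hpd_min, a$hpd_max) else NULL,
      areas = if (!is.null(a) && !is.na(a$areas))
        strsplit(a$areas, ",", fixed = TRUE)[[1]] else NULL,
      extra = if (!is.null(a)) a$extra else NA_character_,
      children = list())
    for (k in kids[[as.character(node)]] %||% integer()) out$children <- c(out$children, list(build(k)))
    out
  }
  build(ntip + 1L)
}

nested_to_chron <- function(root) {
  tips <- list(); internals <- list()
  collect <- function(node) {
    if (!length(node$children)) {
      tips[[length(tips) + 1L]] <<- node
      list(tip = TRUE, idx = length(tips))
    } else {
      ch <- lapply(node$children, collect)
      internals[[length(internals) + 1L]] <<- list(node = node, children = ch)
      list(tip = FALSE, idx = length(internals))
    }
  }
  collect(root)
  ntip <- length(tips); nint <- length(internals)
  # internals were appended post-order; root is the last one
  edge <- matrix(0L, ntip + nint - 1L, 2L); elen <- numeric(nrow(edge))
  labels <- vapply(tips, function(t) t$label %||% stop("unlabeled tip"), "")
  node_label <- character(nint)
  anno <- list()
  e <- 0L
  for (i in seq_len(nint)) {
    rec <- internals[[i]]
    pid <- ntip + i
    node_label[i] <- rec$node$label %||% ""
    for (j in seq_along(rec$children)) {
      ch <- rec$children[[j]]
      cid <- if (ch$tip) ch$idx else ntip + ch$idx
      cage <- if (ch$tip) tips[[ch$idx]]$age else internals[[ch$idx]]$node$age
      e <- e + 1L
      edge[e, ] <- c(pid, cid)
      elen[e] <- rec$node$age - cage
    }
  }
  root_id <- ntip + nint
  # ape requires the root to be node ntip+1: remap internal ids reversing order
  remap <- function(id) if (id <= ntip) id else ntip + (nint + 1L) - (id - ntip)
  edge[, 1] <- vapply(edge[, 1], remap, 0L)
  edge[, 2] <- vapply(edge[, 2], remap, 0L)
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = unname(labels), Nnode = nint,
                        node.label = rev(node_label)),
                   class = "phylo", order = NULL)
  phy <- ape::reorder.phylo(phy, "cladewise")
  # annotations
  rows <- list()
  add_anno <- function(node, id) {
    extra <- node$extra %||% NA_character_
    if ((!is.null(node$support) && !is.na(node$support)) ||
        !is.null(node$hpd) || length(node$areas) || !is.na(extra)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        node = id,
        support = node$support %||% NA_real_,
        hpd_min = if (!is.null(node$hpd)) node$hpd[1] else NA_real_,
        hpd_max = if (!is.null(node$hpd)) node$hpd[2] else NA_real_,
        areas = if (length(node$areas)) paste(node$areas, collapse = ",") else NA_character_,
        extra = extra,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(ntip)) add_anno(tips[[i]], i)
  for (i in seq_len(nint)) add_anno(internals[[i]]$node, remap(ntip + i))
  chronogram(phy, if (length(rows)) do.call(rbind, rows) else NULL)
}

nested_find_mrca <- function(node, labels) {
  # smallest clade containing all `labels`; returns the nested node or NULL
  has_all <- function(n) all(labels %in% nested_tips(n))
  if (!has_all(node)) return(NULL)
  repeat {
    nxt <- NULL
    for (ch in node$children) if (has_all(ch)) { nxt <- ch; break }
    if (is.null(nxt)) return(node)
    node <- nxt
  }
}

nested_tips <- function(node) {
  if (!length(node$children)) return(node$label)
  unlist(lapply(node$children, nested_tips), use.names = FALSE)
}
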