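as_phylo <- function(x) if (inherits(x, "chronogram")) x$phy else x

# Canonical unrooted bipartition table of a tree.
# Returns a named numeric vector: key -> branch length (0 when absent).
# Keys are the tip set on the side NOT containing the reference tip
# (lexicographically smallest label), sorted and ';'-joined.  With
# trivial = TRUE, terminal branches are included.
split_table <- function(phy, trivial = FALSE) {
  phy <- as_phylo(phy)
  if (ape::Ntip(phy) > 2 && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(po)
  all_tips <- sort(po$tip.label)
  ref <- all_tips[1]
  sets <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge)))
    sets[[po$edge[e, 1]]] <- c(sets[[po$edge[e, 1]]], sets[[po$edge[e, 2]]])
  out <- numeric(); keys <- character()
  elen <- po$edge.length %||% rep(0, nrow(po$edge))
  for (e in seq_len(nrow(po$edge))) {
    side <- sets[[po$edge[e, 2]]]
    if (!trivial && (length(side) <= 1L || length(side) >= ntip - 1L)) next
    if (ref %in% side) side <- setdiff(all_tips, side)
    key <- paste(sort(side), collapse = ";")
    i <- match(key, keys)
    if (is.na(i)) { keys <- c(keys, key); out <- c(out, elen[e]) }
    else out[i] <- out[i] + elen[e]   # two root-adjacent edges of one split
  }
  names(out) <- keys
  out
}

# canonical unrooted split key for every internal node of a rooted tree
node_split_keys <- function(phy) {
  phy <- as_phylo(phy)
  keys <- clade_keys(phy)
  all_tips <- sort(phy$tip.label)
  ref <- all_tips[1]
  out <- vapply(unname(keys), function(k) {
    side <- strsplit(k, ";", fixed = TRUE)[[1]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    paste(sort(side), collapse = ";")
  }, "")
  stats::setNames(out, names(keys))
}

check_same_tips <- function(t1, t2) {
  a <- sort(as_phylo(t1)$tip.label); b <- sort(as_phylo(t2)$tip.label)
  if (!identical(a, b)) stop("trees have different tip sets")
  a
}

#' Robinson-Foulds distance, raw and normalized
#'
#' Counts the bipartitions present in one tree but not the other (and
#' vice versa), over non-trivial splits of the unrooted trees.  The
#' normalization divides by the total number of non-trivial splits in
#' both trees, so two maximally different binary trees score 1.
#'
#' @param t1,t2 trees (`phylo` or `chronogram`) on the same tip set,
#'   >= 4 tips.
#' @return list: `raw` (integer), `normalized` (in `[0, 1]`),
#'   `n_splits_1`, `n_splits_2`.
#' @export
rf_distance <- function(t1, t2) {
  tips <- check_same_tips(t1, t2)
  if (length(tips) < 4) stop("need >= 4 tips for an informative RF distance")
  s1 <- names(split_table(t1, trivial = FALSE))
  s2 <- names(split_table(t2, trivial = FALSE))
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  denom <- length(s1) + length(s2)
  list(raw = raw,
       normalized = if (denom == 0) 0 else raw / denom,
       n_splits_1 = length(s1), n_splits_2 = length(s2))
}

#' Squared-Euclidean branch-length distance (branch score)
#'
#' Sum over the union of bipartitions of the squared difference between
#' the branch lengths the two trees assign to each bipartition, with an
#' absent bipartition contributing length 0.  Terminal branches are
#' included, following the Kuhner-Felsenstein branch-score construction.
#' The default normalization divides by the size of the union of
#' bipartitions; `denominator = "sum"` divides by the summed bipartition
#' counts of both trees instead.
#'
#' @param t1,t2 trees with branch lengths on the same tip set.
#' @param denominator `"union"` (default) or `"sum"`.
#' @return list: `raw`, `normalized`, `n_bipartitions` (denominator).
#' @export
branch_score <- function(t1, t2, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  check_same_tips(t1, t2)
  s1 <- split_table(t1, trivial = TRUE)
  s2 <- split_table(t2, trivial = TRUE)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  raw <- sum((l1 - l2)^2)
  denom <- if (denominator == "union") length(keys) else length(s1) + length(s2)
  list(raw = raw, normalized = raw / denom, n_bipartitions = denom)
}

#' All four tree-to-tree distance figures at once
#'
#' @param t1,t2 trees on the same tip set.
#' @param denominator normalization rule for the branch score.
#' @return one-row data frame: `rf_raw`, `rf_normalized`,
#'   `sqeuclid_raw`, `sqeuclid_normalized`.
#' @export
tree_distances <- function(t1, t2, denominator = "union") {
  rf <- rf_distance(t1, t2)
  bs <- branch_score(t1, t2, denominator)
  data.frame(rf_raw = rf$raw, rf_normalized = rf$normalized,
             sqeuclid_raw = bs$raw, sqeuclid_normalized = bs$normalized)
}
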