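#' Neighbor-joining tree from a concatenated supermatrix
#'
#' Distance-based inference used for the offline backbone: pairwise
#' distances with pairwise deletion over the concatenated matrix, then
#' standard neighbor joining.  Rows are ordered lexicographically before
#' agglomeration so ties resolve deterministically; negative inferred
#' branch lengths are clamped to zero with a warning.  Saturated pairs
#' (distance `Inf`) are replaced by 1.25 x the largest finite distance,
#' with a warning.
#'
#' @param mat character matrix (rows = taxa) with `?` for missing cells.
#' @param model distance model (`"JC69"` default, or `"p"`).
#' @return an unrooted `phylo` phylogram.
#' @export
nj_tree <- function(mat, model = "JC69") {
  if (nrow(mat) < 3) stop("need >= 3 taxa")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- alignment_distances(mat, model)
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("zero comparable sites between ", rownames(mat)[bad[1]],
         " and ", rownames(mat)[bad[2]])
  }
  if (any(is.infinite(d))) {
    warning("saturated distance(s) replaced by 1.25 x max finite distance")
    d[is.infinite(d)] <- 1.25 * max(d[is.finite(d)])
  }
  phy <- ape::nj(stats::as.dist(d))
  if (any(phy$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    phy$edge.length[phy$edge.length < 0] <- 0
  }
  phy
}

resample_columns <- function(ncols, partitions = NULL) {
  if (is.null(partitions))
    return(sample.int(ncols, ncols, replace = TRUE))
  unlist(lapply(seq_len(nrow(partitions)), function(i) {
    cols <- partitions$start[i]:partitions$end[i]
    sample(cols, length(cols), replace = TRUE)
  }))
}

#' Bootstrap support for an NJ tree
#'
#' Columns are resampled with replacement (within each partition when a
#' partition table is given), a replicate NJ tree is built per resample,
#' and each internal split of the original tree receives as support the
#' fraction of replicate trees containing it.
#'
#' @param mat supermatrix (character, rows = taxa).
#' @param partitions optional data frame `name`, `start`, `end`.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed (required, for reproducibility).
#' @param model distance model.
#' @return list: `tree` (the original NJ `phylo`), `support` (named
#'   vector, split key -> support in `[0, 1]`), `replicates` (list of
#'   replicate `phylo` trees).
#' @export
bootstrap_support <- function(mat, partitions = NULL, replicates = 100L,
                              seed = 1L, model = "JC69") {
  stopifnot(replicates >= 1L)
  phy <- nj_tree(mat, model)
  reps <- with_seed(seed, lapply(seq_len(replicates), function(i) {
    idx <- resample_columns(ncol(mat), partitions)
    suppressWarnings(nj_tree(mat[, idx, drop = FALSE], model))
  }))
  orig <- names(split_table(phy, trivial = FALSE))
  hits <- stats::setNames(numeric(length(orig)), orig)
  for (r in reps) {
    rs <- names(split_table(r, trivial = FALSE))
    hits[orig %in% rs] <- hits[orig %in% rs] + 1
  }
  list(tree = phy, support = hits / replicates, replicates = reps)
}

# clades (rooted tip subsets) of a tree, as sorted ';'-joined keys
clade_keys <- function(phy) {
  phy <- as_phylo(phy)
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(po)
  sets <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge)))
    sets[[po$edge[e, 1]]] <- c(sets[[po$edge[e, 1]]], sets[[po$edge[e, 2]]])
  keys <- vapply(sets[(ntip + 1L):(ntip + po$Nnode)],
                 function(s) paste(sort(s), collapse = ";"), "")
  stats::setNames(keys, (ntip + 1L):(ntip + po$Nnode))
}

#' Majority-rule consensus of rooted trees
#'
#' Clades occurring in a fraction of trees strictly greater than
#' `threshold` are retained (so two incompatible clades at exactly 0.5
#' are both excluded); unresolved parts collapse to polytomies.  Clade
#' frequencies are stored as node labels.
#'
#' @param trees list of rooted trees on one tip set.
#' @param threshold in `[0.5, 1]`.
#' @return a rooted `phylo`; `node.label` holds clade frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  trees <- lapply(trees, as_phylo)
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!identical(sort(t$tip.label), tips))
    stop("trees have different tip sets")
  n <- length(trees)
  counts <- list()
  for (t in trees) for (key in unique(unname(clade_keys(t))))
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  keys <- names(counts)
  freq <- unlist(counts) / n
  root_key <- paste(tips, collapse = ";")
  keep <- keys[freq > threshold | keys == root_key]
  if (!root_key %in% keep) keep <- c(keep, root_key)
  freq[root_key] <- 1
  clades <- strsplit(keep, ";", fixed = TRUE)
  ord <- order(-lengths(clades))
  clades <- clades[ord]; keep <- keep[ord]
  # nest: parent of each clade is the smallest strictly containing clade
  build <- function(i) {
    members <- clades[[i]]
    inner <- which(vapply(seq_along(clades), function(j)
      j != i && length(clades[[j]]) < length(members) &&
        all(clades[[j]] %in% members), FALSE))
    # direct children: inner clades not contained in another inner clade
    direct <- inner[vapply(inner, function(j)
      !any(vapply(inner, function(k)
        k != j && all(clades[[j]] %in% clades[[k]]), FALSE)), FALSE)]
    used <- unlist(clades[direct])
    loose <- setdiff(members, used)
    parts <- c(lapply(direct, build), as.list(loose))
    paste0("(", paste(unlist(parts), collapse = ","), ")",
           format_num(freq[keep[i]], 6))
  }
  nwk <- paste0(build(1L), ";")
  phy <- ape::read.tree(text = nwk)
  phy$node.label <- as.character(phy$node.label)
  phy
}

#' Map fossil calibrations onto tree nodes
#'
#' Each calibration is placed on the MRCA of its taxa.  Calibrations
#' whose taxa are not all tips of the tree are skipped with a warning;
#' several calibrations resolving to one node are combined (min = max of
#' minima, max = min of maxima); a descendant node whose minimum exceeds
#' an ancestor's maximum is a hard conflict.
#'
#' @param tree a rooted tree (`phylo` or `chronogram`).
#' @param calibrations fossil table (see [read_fossil_table()]).
#' @param partial place on the MRCA of the calibration taxa that are
#'   present as tips (needed when dating an exemplar backbone whose tips
#'   are a subset of the species the fossil references); with the
#'   default `FALSE`, a calibration with any absent taxon is skipped.
#' @return data frame: `node`, `min_age`, `max_age`, `calib_ids`.
#' @export
place_fossils <- function(tree, calibrations, partial = FALSE) {
  phy <- as_phylo(tree)
  placements <- list()
  for (i in seq_len(nrow(calibrations))) {
    taxa <- unique(calibrations$taxa[[i]])
    if (partial) taxa <- intersect(taxa, phy$tip.label)
    if (length(taxa) < 2 || !all(taxa %in% phy$tip.label)) {
      warning("calibration ", calibrations$calib_id[i],
              " skipped: taxa not all present")
      next
    }
    if (length(taxa) < 2)
      stop("calibration ", calibrations$calib_id[i], " resolves to a tip")
    node <- ape::getMRCA(phy, taxa)
    key <- as.character(node)
    p <- placements[[key]] %||% list(node = node, min_age = -Inf,
                                     max_age = Inf, calib_ids = character())
    p$min_age <- max(p$min_age, calibrations$min_age[i])
    mx <- calibrations$max_age[i]
    if (!is.na(mx)) p$max_age <- min(p$max_age, mx)
    p$calib_ids <- c(p$calib_ids, calibrations$calib_id[i])
    placements[[key]] <- p
  }
  if (!length(placements)) stop("no calibration could be placed")
  out <- data.frame(
    node = vapply(placements, `[[`, 0, "node"),
    min_age = vapply(placements, `[[`, 0, "min_age"),
    max_age = vapply(placements, `[[`, 0, "max_age"),
    calib_ids = vapply(placements, function(p) paste(p$calib_ids, collapse = ","), ""))
  rownames(out) <- NULL
  if (any(out$min_age > out$max_age)) stop("calibration min_age exceeds max_age")
  # ancestor/descendant conflicts
  anc <- lapply(out$node, function(n) nodepath_to_root(phy, n))
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i != j && out$node[j] %in% anc[[i]] &&
        out$min_age[i] > out$max_age[j])
      stop("conflicting calibrations: descendant minimum ", out$min_age[i],
           " exceeds ancestor maximum ", out$max_age[j])
  }
  out
}

nodepath_to_root <- function(phy, node) {
  root <- ape::Ntip(phy) + 1L
  path <- integer()
  while (node != root) {
    node <- phy$edge[phy$edge[, 2] == node, 1]
    path <- c(path, node)
  }
  path
}

# Mean-path-length relative node ages of a rooted phylogram:
# each node's age is the mean root-to-tip path length measured through
# it, clamped so every parent is at least as old as its children.
mpl_ages <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- ape::Ntip(po)
  nn <- ntip + po$Nnode
  tipcount <- c(rep(1, ntip), rep(0, po$Nnode))
  sumpath <- numeric(nn)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tipcount[p] <- tipcount[p] + tipcount[ch]
    sumpath[p] <- sumpath[p] + sumpath[ch] + tipcount[ch] * po$edge.length[e]
  }
  ages <- ifelse(tipcount > 0, sumpath / pmax(tipcount, 1), 0)
  ages[seq_len(ntip)] <- 0
  for (e in seq_len(nrow(po$edge)))     # postorder: children before parents
    ages[po$edge[e, 1]] <- max(ages[po$edge[e, 1]], ages[po$edge[e, 2]])
  ages
}

ages_to_chronogram <- function(phy, ages, data = NULL) {
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  chronogram(phy, data)
}

#' Date a phylogram against fossil calibrations (MPL-scale)
#'
#' A deliberately simple, deterministic dating stand-in with the same
#' contract as penalized-likelihood dating: (1) the tree is made
#' ultrametric by mean-path-length smoothing (each internal node's
#' relative age is the mean root-to-tip path length through it, clamped
#' so parents are at least as old as children); (2) all relative ages are
#' multiplied by the single global factor
#' \eqn{f = \max_i(\mathrm{min\_age}_i / \mathrm{relative\_age}_i)} over
#' the fossil placements, which is the smallest global scaling satisfying
#' every minimum-age constraint; (3) any maximum-age constraint violated
#' after scaling is a hard error.  This is rate smoothing by global
#' scaling, not penalized likelihood; external dating engines can be
#' slotted in via the adapter hooks of the pipeline.
#'
#' @param phy a phylogram (`phylo`); if unrooted it is midpoint-rooted
#'   (or rooted on `outgroup` when given).
#' @param placements output of [place_fossils()] (nodes must refer to
#'   the rooted tree; when `phy` needs rooting first, pass the fossil
#'   table via `calibrations` instead and placement happens internally).
#' @param calibrations optional fossil table, placed after rooting.
#' @param outgroup optional tip labels to root on.
#' @param partial see [place_fossils()].
#' @return a dated, ultrametric [chronogram()].
#' @export
date_tree <- function(phy, placements = NULL, calibrations = NULL,
                      outgroup = NULL, partial = FALSE) {
  phy <- as_phylo(phy)
  if (!is.null(outgroup)) phy <- ape::root(phy, outgroup, resolve.root = TRUE)
  else if (!ape::is.rooted(phy)) phy <- phangorn::midpoint(phy)
  if (is.null(placements)) {
    if (is.null(calibrations)) stop("need placements or calibrations")
    placements <- place_fossils(phy, calibrations, partial = partial)
  }
  rel <- mpl_ages(phy)
  if (max(rel) <= 0) stop("zero-depth tree cannot be dated")
  rel_at <- rel[placements$node]
  if (any(rel_at <= 0))
    stop("calibration placed on a zero-age node")
  f <- max(placements$min_age / rel_at)
  ages <- rel * f
  over <- ages[placements$node] > placements$max_age + 1e-9
  if (any(over))
    stop("max-age constraint unsatisfiable by global scaling for node(s) ",
         paste(placements$node[over], collapse = ", "))
  chron <- ages_to_chronogram(phy, ages)
  validate_chronogram(chron)
  chron
}

#' Attach node-age HPDs from a sample of dated trees
#'
#' Every tree in `sample` is dated independently with the same fossil
#' table; for each clade of the primary dated tree, the 2.5% and 97.5%
#' quantiles of the ages that the sample assigns to that clade become
#' its `hpd_min`/`hpd_max`.
#'
#' @param chron the primary dated [chronogram()].
#' @param sample list of phylograms (e.g. bootstrap replicates).
#' @param calibrations fossil table used to date each sample tree.
#' @param outgroup optional rooting outgroup for sample trees.
#' @param partial see [place_fossils()].
#' @return `chron` with HPD annotations on internal nodes.
#' @export
date_with_sample <- function(chron, sample, calibrations, outgroup = NULL,
                             partial = FALSE) {
  chron <- as_chronogram(chron)
  dated <- lapply(sample, function(t)
    tryCatch(date_tree(t, calibrations = calibrations, outgroup = outgroup,
                       partial = partial),
             error = function(e) NULL))
  dated <- Filter(Negate(is.null), dated)
  if (!length(dated)) return(chron)
  age_by_key <- list()
  for (d in dated) {
    keys <- clade_keys(d$phy)
    ages <- node_ages(d)
    for (i in seq_along(keys)) {
      nd <- as.integer(names(keys)[i])
      age_by_key[[keys[i]]] <- c(age_by_key[[keys[i]]], ages[nd])
    }
  }
  main_keys <- clade_keys(chron$phy)
  main_ages <- node_ages(chron)
  for (i in seq_along(main_keys)) {
    obs <- age_by_key[[main_keys[i]]]
    if (length(obs) >= 2) {
      nd <- as.integer(names(main_keys)[i])
      q <- stats::quantile(obs, c(0.025, 0.975), names = FALSE)
      old <- anno_lookup(chron, nd)
      chron <- set_anno(chron, nd,
                        support = old$support %||% NA_real_,
                        hpd_min = min(q[1], main_ages[nd]),
                        hpd_max = max(q[2], main_ages[nd]))
    }
  }
  chron
}
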