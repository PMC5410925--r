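#' Average pairwise divergence of an alignment
#'
#' Mean of all finite pairwise distances among rows.  Saturated pairs
#' (`Inf` under JC69) are excluded from the mean but counted; pairs with
#' no comparable sites are likewise excluded.  Used to keep saturated
#' alignments out of the backbone supermatrix.
#'
#' @param mat aligned character matrix with >= 2 rows.
#' @param model `"JC69"` or `"p"`.
#' @return the mean distance, with attribute `saturated` (count of
#'   excluded saturated pairs); errors if every pair is saturated.
#' @export
average_divergence <- function(mat, model = "JC69") {
  if (nrow(mat) < 2) stop("need >= 2 rows")
  d <- alignment_distances(mat, model)
  v <- d[upper.tri(d)]
  n_sat <- sum(is.infinite(v))
  v <- v[is.finite(v)]
  if (!length(v)) stop("all pairs saturated or incomparable")
  structure(mean(v), saturated = n_sat)
}

#' Species-by-alignment occupancy matrix
#'
#' @param alignments named list of aligned matrices (rownames = species).
#' @param species optional row universe; defaults to all species seen.
#' @return logical matrix, species x alignment.
#' @export
occupancy_matrix <- function(alignments, species = NULL) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be named")
  species <- sort(species %||% unique(unlist(lapply(alignments, rownames))))
  occ <- vapply(alignments, function(a) species %in% rownames(a),
                logical(length(species)))
  occ <- matrix(occ, nrow = length(species),
                dimnames = list(species, names(alignments)))
  occ
}

#' Greedy knapsack assembly of a minimally sparse supermatrix
#'
#' Implements the greedy approximation for packing candidate alignments
#' into a supermatrix under per-species participation constraints.
#' Exemplar species are visited in ascending order of participation in
#' the candidate alignments (rarely sequenced species first); for the
#' focal species its alignments are visited in descending taxon coverage,
#' and selected until the focal species occurs in `max_markers` selected
#' alignments or its candidates are exhausted.  Afterwards, species
#' occurring in fewer than `min_markers` selected alignments are dropped
#' and reported.  All order ties are broken lexicographically, making the
#' selection deterministic and independent of input order.
#'
#' @param alignments named list of aligned matrices (full rows).
#' @param exemplar_species character vector of backbone species ids.
#' @param min_markers,max_markers per-species participation bounds.
#' @param max_avg_divergence candidates above this average pairwise
#'   divergence are excluded up front (default 0.25).
#' @param model distance model for the divergence filter.
#' @return list: `selected` (alignment ids in selection order),
#'   `retained` (species ids), `dropped` (data frame `species_id`,
#'   `n_markers`), `excluded_alignments` (failed the divergence filter),
#'   `occupancy` (candidate occupancy matrix over exemplar species).
#' @export
assemble_supermatrix <- function(alignments, exemplar_species,
                                 min_markers = 1L, max_markers = 3L,
                                 max_avg_divergence = 0.25, model = "JC69") {
  stopifnot(min_markers >= 1L, max_markers >= min_markers)
  # restrict to exemplar rows
  cand <- lapply(alignments, function(a)
    a[intersect(rownames(a), exemplar_species), , drop = FALSE])
  cand <- cand[vapply(cand, nrow, 0L) >= 1L]
  excluded <- character()
  for (id in names(cand)) {
    if (nrow(cand[[id]]) >= 2) {
      div <- tryCatch(as.numeric(average_divergence(cand[[id]], model)),
                      error = function(e) Inf)
      if (div > max_avg_divergence) excluded <- c(excluded, id)
    }
  }
  cand <- cand[setdiff(names(cand), excluded)]
  if (!length(cand)) stop("no alignment survives the divergence filter")
  occ <- occupancy_matrix(cand, species = sort(unique(unlist(lapply(cand, rownames)))))
  participation <- rowSums(occ)
  coverage <- colSums(occ)
  sp_order <- rownames(occ)[order(participation, rownames(occ))]
  selected <- character()
  for (sp in sp_order) {
    ids <- colnames(occ)[occ[sp, ]]
    ids <- ids[order(-coverage[ids], ids)]
    for (id in ids) {
      if (sum(occ[sp, selected]) >= max_markers) break
      if (!id %in% selected) selected <- c(selected, id)
    }
  }
  counts <- rowSums(occ[, selected, drop = FALSE])
  retained <- rownames(occ)[counts >= min_markers]
  dropped <- data.frame(species_id = rownames(occ)[counts < min_markers],
                        n_markers = unname(counts[counts < min_markers]))
  # an alignment whose species were all dropped carries no data
  keep <- vapply(selected, function(id) any(occ[retained, id]), TRUE)
  selected <- selected[keep]
  list(selected = selected, retained = sort(retained), dropped = dropped,
       excluded_alignments = excluded, occupancy = occ)
}

#' Concatenate selected alignments into a supermatrix
#'
#' @param alignments named list of aligned matrices.
#' @param selected alignment ids, in selection order (partition order).
#' @param retained species ids forming the rows.
#' @return list: `matrix` (character, `?` for missing cells) and
#'   `partitions` (data frame `name`, `start`, `end`, 1-based inclusive).
#' @export
concatenate_alignments <- function(alignments, selected, retained) {
  if (!length(selected)) stop("empty selection")
  retained <- sort(retained)
  blocks <- list(); parts <- list(); at <- 0L
  for (id in selected) {
    a <- alignments[[id]]
    if (is.null(a)) stop("unknown alignment id: ", id)
    if (anyDuplicated(rownames(a)))
      stop("duplicate species row in alignment ", id)
    block <- matrix("?", length(retained), ncol(a),
                    dimnames = list(retained, NULL))
    common <- intersect(retained, rownames(a))
    block[common, ] <- a[common, , drop = FALSE]
    blocks[[id]] <- block
    parts[[id]] <- data.frame(name = id, start = at + 1L, end = at + ncol(a))
    at <- at + ncol(a)
  }
  list(matrix = do.call(cbind, blocks),
       partitions = do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Marker-graph diagnostics of an occupancy matrix
#'
#' The marker graph connects two species when they share at least one
#' alignment.  Its density and mean shortest-path length summarize how
#' well the chosen markers tie the taxa together; a fragmented graph
#' (several components) means some taxa cannot be placed relative to
#' others at all.
#'
#' @param occupancy logical species x alignment matrix.
#' @return list: `density` (2E / V(V-1)), `mean_path_length` (average
#'   over pairs within the largest connected component; `NA` when that
#'   component is a single species), `components` (count).
#' @export
marker_graph_stats <- function(occupancy) {
  if (nrow(occupancy) < 2) stop("need >= 2 species")
  v <- rownames(occupancy)
  adj <- (occupancy %*% t(occupancy)) > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  mpl <- if (igraph::vcount(sub) < 2) NA_real_ else {
    dm <- igraph::distances(sub)
    mean(dm[upper.tri(dm)])
  }
  list(density = igraph::edge_density(g),
       mean_path_length = mpl,
       components = comp$no)
}
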