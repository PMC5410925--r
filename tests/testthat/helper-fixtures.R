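# Fixture builders and independent reference implementations used as
# oracles.  Everything is generated in code; no data files.

mk_cluster <- function(seqs, species = NULL, id = "c1", seed = NULL,
                       aligned = FALSE) {
  ids <- names(seqs) %||% paste0("q", seq_along(seqs))
  phylograft::seq_cluster(id, ids, species %||% ids, unname(unlist(seqs)),
                          seed_id = seed %||% ids[1], aligned = aligned)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_alignment <- function(species, len, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), length(species) * len,
                     replace = TRUE),
              nrow = length(species), dimnames = list(species, NULL))
  m
}

rand_ultrametric <- function(n, seed, scale = 10) {
  set.seed(seed)
  phy <- ape::rcoal(n, tip.label = sprintf("t%02d", seq_len(n)))
  phy$edge.length <- phy$edge.length * scale / max(ape::branching.times(phy))
  phy
}

# ---- step-by-step reference simulator of the greedy knapsack ---------------
# Independent, literal transcription of the stated rules; deliberately
# naive (no shared code with assemble_supermatrix).
reference_knapsack <- function(occ, min_markers, max_markers) {
  participation <- rowSums(occ)
  coverage <- colSums(occ)
  species_order <- rownames(occ)[order(participation, rownames(occ))]
  selected <- character(0)
  for (sp in species_order) {
    cands <- colnames(occ)[occ[sp, ] == 1]
    cands <- cands[order(-coverage[cands], cands)]
    for (al in cands) {
      count <- if (length(selected)) sum(occ[sp, selected]) else 0
      if (count >= max_markers) break
      if (!(al %in% selected)) selected <- c(selected, al)
    }
  }
  counts <- sapply(rownames(occ), function(sp)
    if (length(selected)) sum(occ[sp, selected]) else 0)
  retained <- rownames(occ)[counts >= min_markers]
  dropped <- rownames(occ)[counts < min_markers]
  keep <- selected[sapply(selected, function(al)
    sum(occ[retained, al] == 1) > 0)]
  list(selected = keep, retained = sort(retained), dropped = sort(dropped))
}

rand_occupancy <- function(seed, max_sp = 12, max_al = 12) {
  set.seed(seed)
  ns <- sample(3:max_sp, 1); na <- sample(2:max_al, 1)
  occ <- matrix(rbinom(ns * na, 1, runif(1, 0.3, 0.8)), ns, na,
                dimnames = list(sprintf("S%02d", 1:ns),
                                sprintf("A%02d", 1:na)))
  # every species in >= 1 alignment, every alignment non-empty
  for (i in 1:ns) if (!any(occ[i, ] == 1)) occ[i, sample(na, 1)] <- 1
  for (j in 1:na) if (!any(occ[, j] == 1)) occ[sample(ns, 1), j] <- 1
  occ
}

# turn a 0/1 occupancy matrix into dummy alignments so the exported
# assembler (which works from alignments) can be run on it
occupancy_to_alignments <- function(occ) {
  out <- list()
  for (j in seq_len(ncol(occ))) {
    sp <- rownames(occ)[occ[, j] == 1]
    out[[colnames(occ)[j]]] <-
      matrix("A", length(sp), 4, dimnames = list(sp, NULL))
  }
  out
}

# ---- brute-force exemplar tallies ------------------------------------------
brute_force_exemplars <- function(alignments, taxa_table, genus) {
  sp_all <- taxa_table$species_id[taxa_table$genus == genus]
  tally <- list()
  for (aln in alignments) {
    sp <- sort(intersect(rownames(aln), sp_all))
    k <- length(sp)
    if (k < 2) next
    pairs <- t(combn(sp, 2))
    d <- apply(pairs, 1, function(p)
      tryCatch(phylograft::pairwise_distance(aln[p[1], ], aln[p[2], ]),
               error = function(e) -Inf))
    d[is.na(d)] <- -Inf
    best <- which(d == max(d))[1]           # pairs already lexicographic
    key <- paste(pairs[best, ], collapse = "|")
    w <- k * (k - 1) / 2 - 1
    tally[[key]] <- (tally[[key]] %||% 0) + w
  }
  if (!length(tally)) return(NULL)
  t2 <- unlist(tally)
  win <- sort(names(t2)[t2 == max(t2)])[1]
  list(pair = strsplit(win, "|", fixed = TRUE)[[1]], weight = max(t2))
}

# random small taxa table: species G<g>_s<i>
rand_taxa <- function(n_genera, max_per_genus, seed) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genera)) {
    k <- sample(seq_len(max_per_genus), 1)
    for (i in seq_len(k))
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sprintf("G%d_s%d", g, i),
        species_name = sprintf("G%d_s%d", g, i),
        genus = sprintf("G%d", g), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# enumerate all unrooted binary topologies on the given tips (as multiPhylo)
all_unrooted_topologies <- function(tips) {
  phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
}
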