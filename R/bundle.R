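# Partition a tree's tips into k monophyletic groups by repeatedly
# splitting the largest remaining clade into its children.
split_tree_genera <- function(phy, k) {
  ntip <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  tipset <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tipset), use.names = FALSE)
  }
  clades <- kids[[as.character(ntip + 1L)]]
  while (length(clades) < k) {
    sizes <- vapply(clades, function(n) length(tipset(n)), 0L)
    internal <- which(clades > ntip)
    if (!length(internal)) break
    pick <- internal[order(-sizes[internal], clades[internal])][1]
    clades <- c(clades[-pick], kids[[as.character(clades[pick])]])
  }
  groups <- lapply(clades, tipset)
  groups[order(-lengths(groups), vapply(groups, min, ""))]
}

# six exchangeabilities in ACGT order (AC, AG, AT, CG, CT, GT)
model_Q <- function(model, kappa = 4, Q = NULL) {
  switch(model,
         JC = rep(1, 6),
         K80 = c(1, kappa, 1, 1, kappa, 1),
         HKY = c(1, kappa, 1, 1, kappa, 1),
         GTR = Q %||% stop("GTR needs an explicit Q"),
         stop("unknown model: ", model))
}

#' Generate a synthetic reference bundle
#'
#' The self-contained study system for validating the divide-and-graft
#' pipeline: a birth-death "true" chronogram, monophyletic genera carved
#' out of it, aligned sequence clusters simulated along it, a patchy
#' occupancy pattern (a few universally sequenced barcode-like markers
#' plus partially sampled ones), and fossil calibrations placed on
#' genus-closed internal nodes with their true ages as minimum ages.
#'
#' @param n_species extant species on the true tree.
#' @param n_genera number of monophyletic genera to carve out.
#' @param lambda,mu birth-death rates (per lineage per Ma).
#' @param n_clusters number of sequence clusters (markers).
#' @param seq_length alignment length per cluster, bp.
#' @param model substitution model (`"JC"`, `"K80"`, `"HKY"`, `"GTR"`).
#' @param kappa transition/transversion exchangeability for K80/HKY.
#' @param bf base frequencies (ACGT).
#' @param shape Gamma shape for among-site rate variation (NA = none).
#' @param rate clock rate, substitutions per site per Ma.
#' @param full_clusters how many clusters cover every species.
#' @param coverage inclusion probability per species for the remaining
#'   clusters.
#' @param calib_depths fossil calibration points, as fractions of the
#'   root age.
#' @param seed master RNG seed.
#' @return list: `tree` (true [chronogram()]), `taxa`, `clusters`
#'   (named list of aligned matrices), `fossils`, `params`.
#' @export
simulate_reference_bundle <- function(n_species = 40L, n_genera = 8L,
                                      lambda = 0.3, mu = 0.1,
                                      n_clusters = 6L, seq_length = 1500L,
                                      model = "HKY", kappa = 4,
                                      bf = c(0.3, 0.2, 0.2, 0.3),
                                      shape = 0.5, rate = 0.004,
                                      full_clusters = 2L, coverage = 0.7,
                                      calib_depths = c(0.55, 0.8),
                                      seed = 1L) {
  chron <- simulate_bd_tree(lambda, mu, n_species, seed = derive_seed(seed, 1))
  phy <- chron$phy
  groups <- split_tree_genera(phy, n_genera)
  rename <- character()
  for (i in seq_along(groups)) {
    sp <- sort(groups[[i]])
    rename[sp] <- sprintf("G%d_s%02d", i, seq_along(sp))
  }
  phy$tip.label <- unname(rename[phy$tip.label])
  chron <- chronogram(phy)
  taxa <- data.frame(species_id = sort(phy$tip.label),
                     species_name = sort(phy$tip.label),
                     genus = sub("_s[0-9]+$", "", sort(phy$tip.label)),
                     stringsAsFactors = FALSE)
  spec <- list(Q = model_Q(model, kappa), bf = bf,
               shape = if (model == "JC") NA_real_ else shape,
               length = seq_length, rate = rate)
  if (is.na(shape)) spec$shape <- NA_real_
  clusters <- list()
  occ_seed <- derive_seed(seed, 2)
  subsets <- with_seed(occ_seed, {
    lapply(seq_len(n_clusters), function(i) {
      if (i <= full_clusters) return(sort(phy$tip.label))
      repeat {
        sel <- phy$tip.label[stats::runif(n_species) < coverage]
        if (length(sel) >= 4) return(sort(sel))
      }
    })
  })
  for (i in seq_len(n_clusters)) {
    m <- simulate_alignment(chron, spec, subsets[[i]],
                            seed = derive_seed(seed, 20 + i))
    if (is_variable_alignment(m))
      clusters[[sprintf("cl%02d", i)]] <- m
  }
  fossils <- pick_fossil_calibrations(chron, taxa, calib_depths)
  list(tree = chron, taxa = taxa, clusters = clusters, fossils = fossils,
       params = list(n_species = n_species, n_genera = n_genera,
                     lambda = lambda, mu = mu, n_clusters = n_clusters,
                     seq_length = seq_length, model = model, kappa = kappa,
                     bf = bf, shape = shape, rate = rate, seed = seed))
}

#' Derive perfect fossil calibrations from a known tree
#'
#' Picks internal nodes whose clades are unions of whole genera
#' ("genus-closed" nodes, so the node is recoverable as an MRCA of
#' exemplars on a backbone) with true ages nearest the requested
#' fractions of the root age, and emits each node's true age as a
#' minimum-age calibration on its full descendant species set.  This is
#' the best-case fossil scenario used for validating the dating and
#' grafting machinery against a known truth.
#'
#' @param tree the true [chronogram()].
#' @param taxa_table taxa table matching the tree's tips.
#' @param calib_depths fractions of the root age to calibrate near.
#' @return a fossil calibration data frame (list column `taxa`).
#' @export
pick_fossil_calibrations <- function(tree, taxa_table,
                                     calib_depths = c(0.55, 0.8)) {
  chron <- as_chronogram(tree)
  phy <- chron$phy
  ages <- node_ages(chron)
  keys <- clade_keys(phy)
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  closed <- vapply(strsplit(unname(keys), ";", fixed = TRUE), function(tp) {
    gs <- unique(genus_of[tp])
    length(gs) >= 2 &&
      setequal(tp, taxa_table$species_id[taxa_table$genus %in% gs])
  }, TRUE)
  cand_nodes <- as.integer(names(keys))[closed]
  fossils <- list()
  used <- integer()
  for (d in calib_depths) {
    target <- d * max(ages)
    avail <- setdiff(cand_nodes, used)
    if (!length(avail)) break
    node <- avail[which.min(abs(ages[avail] - target))]
    used <- c(used, node)
    row <- data.frame(calib_id = sprintf("f%d", length(fossils) + 1L),
                      min_age = ages[node], max_age = NA_real_)
    row$taxa <- list(ape::extract.clade(phy, node)$tip.label)
    fossils[[length(fossils) + 1L]] <- row
  }
  if (!length(fossils)) stop("no genus-closed internal node to calibrate")
  do.call(rbind, fossils)
}

#' Write a reference bundle to a directory
#'
#' Emits `truth.nwk`, `taxa.tsv`, `fossils.tsv`, `occupancy.tsv` and one
#' FASTA per cluster under `clusters/` — the documented input layout of
#' the pipeline stages.
#'
#' @param bundle from [simulate_reference_bundle()] (or a replicate).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "clusters"), recursive = TRUE, showWarnings = FALSE)
  write_tree(bundle$tree, file.path(dir, "truth.nwk"))
  write_taxa_table(bundle$taxa, file.path(dir, "taxa.tsv"))
  if (!is.null(bundle$fossils))
    write_fossil_table(bundle$fossils, file.path(dir, "fossils.tsv"))
  for (id in names(bundle$clusters))
    write_alignment(bundle$clusters[[id]],
                    file.path(dir, "clusters", paste0(id, ".fasta")))
  occ <- occupancy_matrix(bundle$clusters)
  utils::write.table(data.frame(species_id = rownames(occ),
                                ifelse(occ, 1L, 0L), check.names = FALSE),
                     file.path(dir, "occupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
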