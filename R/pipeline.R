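#' Pipeline configuration
#'
#' Collects every knob of the divide-and-graft pipeline in one list with
#' the package defaults.  All randomness is controlled by `seed` (no
#' wall-clock seeding); the configuration in force is serialized into
#' each stage's manifest.
#'
#' @param dir working directory of the run.
#' @param seed master RNG seed.
#' @param ... overrides for any default field.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, seed = 1L, ...) {
  cfg <- list(
    dir = dir, seed = as.integer(seed),
    per_species_keep = 1L,
    kmer_size = 8L, min_similarity = 0.5,
    min_shared_intra = 1L, min_shared_inter = 1L,
    min_markers = 1L, max_markers = 3L, max_avg_divergence = 0.25,
    model = "JC69",
    nboot = 100L, clade_nboot = 0L,
    consensus_threshold = 0.5,
    max_clade_size = 100L,
    graft_mode = "error",
    bin_width = 5,
    outgroup = NULL,
    generate = NULL, treedist = NULL, dispersal = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields override [pipeline_config()] defaults.
#' @param dir working directory (defaults to the YAML's directory).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  y$dir <- y$dir %||% dir
  do.call(pipeline_config, y)
}

PIPELINE_STAGES <- c("replicate", "reduce", "merge", "exemplars",
                     "supermatrix", "bbinfer", "bbdate", "decompose",
                     "cladeinfer", "graft", "treedist", "dispersal")

need_artifact <- function(config, rel, produced_by) {
  p <- file.path(config$dir, rel)
  if (!file.exists(p))
    stop("missing upstream artifact '", rel, "': run stage '",
         produced_by, "' first", call. = FALSE)
  p
}

# Gap-free alignments (e.g. simulated ones) cannot be told from unaligned
# equal-length sequences on re-read; inside the pipeline, equal length is
# taken as aligned.
ensure_aligned <- function(cl) {
  if (!cl$aligned && length(unique(nchar(cl$seqs))) == 1L) cl$aligned <- TRUE
  cl
}

read_cluster_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  cl <- lapply(files, function(f) ensure_aligned(read_fasta_cluster(f)))
  stats::setNames(cl, vapply(cl, `[[`, "", "cluster_id"))
}

read_alignment_dir <- function(dir) {
  lapply(read_cluster_dir(dir), cluster_to_alignment)
}

# first existing alignment directory in pipeline precedence order
alignment_input_dir <- function(config) {
  for (d in c("merged", "reduced", "clusters")) {
    p <- file.path(config$dir, d)
    if (dir.exists(p) && length(list.files(p, pattern = "\\.fasta$"))) return(p)
  }
  stop("no cluster directory found: run stage 'replicate' or provide clusters/",
       call. = FALSE)
}

write_manifest <- function(config, stage, inputs, outputs) {
  mdir <- file.path(config$dir, "manifests")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    stage = stage,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    config = config[setdiff(names(config), c("dir"))],
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(mdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

parse_partition_sidecar <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^(\\S+) = ([0-9]+)-([0-9]+)$", lines))
  do.call(rbind, lapply(m, function(x)
    data.frame(name = x[2], start = as.integer(x[3]), end = as.integer(x[4]))))
}

# collapse internal nodes with support below the threshold into polytomies
collapse_weak_splits <- function(chron, threshold = 0.5) {
  chron <- as_chronogram(chron)
  root <- chron_to_nested(chron)
  walk <- function(node) {
    newkids <- list()
    for (ch in node$children) {
      ch2 <- walk(ch)
      if (length(ch2$children) && !is.null(ch2$support) &&
          !is.na(ch2$support) && ch2$support < threshold) {
        newkids <- c(newkids, ch2$children)
      } else newkids <- c(newkids, list(ch2))
    }
    node$children <- newkids
    node
  }
  nested_to_chron(walk(root))$phy
}

#' Run one pipeline stage
#'
#' Stages consume and produce only documented files under the working
#' directory, so external engines can be slotted in between stages by
#' hand.  Re-running a stage with identical inputs and configuration
#' reproduces its outputs byte for byte.  A manifest (input checksums,
#' configuration, output names) is written per stage under `manifests/`.
#'
#' Stage names: `replicate` (generate or replicate a dataset), `reduce`
#' (per-species sequence selection), `merge` (seed-similarity cluster
#' merging + profile alignment), `exemplars` (sparse-taxon filter +
#' exemplar selection), `supermatrix` (greedy knapsack + concatenation),
#' `bbinfer` (NJ backbone + bootstrap), `bbdate` (fossil calibration),
#' `decompose` (monophyly assessment + clade tasks), `cladeinfer`
#' (relative-time clade trees), `graft` (rescale + graft), `treedist`,
#' `dispersal`.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return list of output paths, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir <- config$dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
               replicate = stage_replicate, reduce = stage_reduce,
               merge = stage_merge, exemplars = stage_exemplars,
               supermatrix = stage_supermatrix, bbinfer = stage_bbinfer,
               bbdate = stage_bbdate, decompose = stage_decompose,
               cladeinfer = stage_cladeinfer, graft = stage_graft,
               treedist = stage_treedist, dispersal = stage_dispersal)
  fn(config)
}

#' Run a sequence of pipeline stages
#'
#' @param config a [pipeline_config()].
#' @param stages stage names in order; the default is the full
#'   divide-and-graft chain after data generation.
#' @return list of per-stage outputs, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("reduce", "merge", "exemplars",
                                    "supermatrix", "bbinfer", "bbdate",
                                    "decompose", "cladeinfer", "graft")) {
  out <- lapply(stages, run_stage, config = config)
  invisible(stats::setNames(out, stages))
}

stage_replicate <- function(config) {
  dir <- config$dir
  if (!is.null(config$generate)) {
    bundle <- do.call(simulate_reference_bundle,
                      c(config$generate, list(seed = config$seed)))
    write_reference_bundle(bundle, dir)
    outputs <- c(file.path(dir, c("truth.nwk", "taxa.tsv", "fossils.tsv",
                                  "occupancy.tsv")),
                 list.files(file.path(dir, "clusters"), full.names = TRUE))
    write_manifest(config, "replicate", character(), outputs)
    return(invisible(outputs))
  }
  truth <- need_artifact(config, "truth.nwk", "replicate")
  taxa_p <- need_artifact(config, "taxa.tsv", "replicate")
  reference <- list(tree = read_tree(truth),
                    clusters = read_alignment_dir(file.path(dir, "clusters")),
                    taxa = read_taxa_table(taxa_p))
  rep <- replicate_dataset(reference, seed = config$seed)
  rep_dir <- file.path(dir, "replicate")
  fossils <- pick_fossil_calibrations(rep$tree, rep$taxa)
  write_reference_bundle(list(tree = rep$tree, taxa = rep$taxa,
                              clusters = rep$clusters, fossils = fossils),
                         rep_dir)
  utils::write.table(rep$summary, file.path(rep_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- list.files(rep_dir, recursive = TRUE, full.names = TRUE)
  write_manifest(config, "replicate", c(truth, taxa_p), outputs)
  invisible(outputs)
}

stage_reduce <- function(config) {
  cdir <- need_artifact(config, "clusters", "replicate")
  clusters <- read_cluster_dir(cdir)
  out_dir <- file.path(config$dir, "reduced")
  dir.create(out_dir, showWarnings = FALSE)
  outputs <- character()
  for (cl in clusters) {
    red <- reduce_cluster(cl, keep = config$per_species_keep)
    p <- file.path(out_dir, paste0(red$cluster_id, ".fasta"))
    write_fasta_cluster(red, p)
    outputs <- c(outputs, p)
  }
  write_manifest(config, "reduce",
                 list.files(cdir, full.names = TRUE), outputs)
  invisible(outputs)
}

stage_merge <- function(config) {
  in_dir <- need_artifact(config, "reduced", "reduce")
  clusters <- read_cluster_dir(in_dir)
  groups <- merge_sister_clusters(clusters,
                                  kmer_size = config$kmer_size,
                                  min_similarity = config$min_similarity)
  out_dir <- file.path(config$dir, "merged")
  dir.create(out_dir, showWarnings = FALSE)
  outputs <- character()
  for (gid in names(groups)) {
    members <- clusters[groups[[gid]]]
    merged <- if (length(members) == 1L) members[[1L]] else {
      if (!all(vapply(members, `[[`, TRUE, "aligned")))
        stop("cluster group ", gid, " holds unaligned members: run an ",
             "external aligner adapter on them first")
      merge_cluster_group(members, merged_id = gid)
    }
    merged <- reduce_cluster(merged, keep = 1L)  # one row per species
    p <- file.path(out_dir, paste0(gid, ".fasta"))
    write_fasta_cluster(merged, p)
    outputs <- c(outputs, p)
  }
  gtab <- data.frame(group = rep(names(groups), lengths(groups)),
                     cluster = unlist(groups))
  gp <- file.path(out_dir, "groups.tsv")
  utils::write.table(gtab, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "merge", list.files(in_dir, full.names = TRUE),
                 c(outputs, gp))
  invisible(outputs)
}

stage_exemplars <- function(config) {
  taxa <- read_taxa_table(need_artifact(config, "taxa.tsv", "replicate"))
  in_dir <- alignment_input_dir(config)
  alignments <- read_alignment_dir(in_dir)
  filt <- filter_sparse_taxa(alignments, taxa,
                             min_shared_intra = config$min_shared_intra,
                             min_shared_inter = config$min_shared_inter)
  kept <- lapply(alignments, function(m)
    m[intersect(rownames(m), filt$retained), , drop = FALSE])
  kept <- kept[vapply(kept, nrow, 0L) > 0L]
  ex <- select_exemplars(kept, taxa, model = config$model)
  p1 <- file.path(config$dir, "exemplars.tsv")
  p2 <- file.path(config$dir, "excluded_taxa.tsv")
  utils::write.table(ex, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(filt$excluded, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, "exemplars",
                 c(list.files(in_dir, full.names = TRUE),
                   file.path(config$dir, "taxa.tsv")), c(p1, p2))
  invisible(c(p1, p2))
}

stage_supermatrix <- function(config) {
  in_dir <- alignment_input_dir(config)
  alignments <- read_alignment_dir(in_dir)
  ex <- utils::read.delim(need_artifact(config, "exemplars.tsv", "exemplars"),
                          stringsAsFactors = FALSE)
  exsp <- exemplar_species(ex)
  asm <- assemble_supermatrix(alignments, exsp,
                              min_markers = config$min_markers,
                              max_markers = config$max_markers,
                              max_avg_divergence = config$max_avg_divergence,
                              model = config$model)
  restricted <- lapply(alignments, function(a)
    a[intersect(rownames(a), exsp), , drop = FALSE])
  conc <- concatenate_alignments(restricted, asm$selected, asm$retained)
  dir <- config$dir
  phy_p <- file.path(dir, "supermatrix.phy")
  write_supermatrix(conc$matrix, conc$partitions, phy_p, format = "phylip")
  fasta_p <- file.path(dir, "supermatrix.fasta")
  write_alignment(conc$matrix, fasta_p)
  sel_p <- file.path(dir, "selection.tsv")
  utils::write.table(
    data.frame(alignment = asm$selected, order = seq_along(asm$selected)),
    sel_p, sep = "\t", quote = FALSE, row.names = FALSE)
  drop_p <- file.path(dir, "dropped_species.tsv")
  utils::write.table(asm$dropped, drop_p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  occ_p <- file.path(dir, "occupancy_exemplars.tsv")
  utils::write.table(data.frame(species_id = rownames(asm$occupancy),
                                ifelse(asm$occupancy, 1L, 0L),
                                check.names = FALSE),
                     occ_p, sep = "\t", quote = FALSE, row.names = FALSE)
  stats <- marker_graph_stats(asm$occupancy[, asm$selected, drop = FALSE])
  mg_p <- file.path(dir, "marker_graph.json")
  jsonlite::write_json(stats, mg_p, auto_unbox = TRUE, digits = NA)
  outputs <- c(phy_p, paste0(phy_p, ".partitions"), fasta_p, sel_p,
               drop_p, occ_p, mg_p)
  write_manifest(config, "supermatrix",
                 c(list.files(in_dir, full.names = TRUE),
                   file.path(dir, "exemplars.tsv")), outputs)
  invisible(outputs)
}

stage_bbinfer <- function(config) {
  fasta_p <- need_artifact(config, "supermatrix.fasta", "supermatrix")
  part_p <- need_artifact(config, "supermatrix.phy.partitions", "supermatrix")
  mat <- read_alignment(fasta_p)
  partitions <- parse_partition_sidecar(part_p)
  bs <- bootstrap_support(mat, partitions, replicates = config$nboot,
                          seed = config$seed, model = config$model)
  phy <- bs$tree
  keys <- node_split_keys(phy)
  rows <- list()
  for (nd in names(keys)) {
    s <- bs$support[keys[[nd]]]
    if (!is.na(s))
      rows[[length(rows) + 1L]] <- data.frame(node = as.integer(nd),
                                              support = unname(s))
  }
  chron <- chronogram(phy, if (length(rows)) do.call(rbind, rows) else NULL)
  bb_p <- file.path(config$dir, "backbone.nwk")
  write_tree(chron, bb_p)
  boot <- bs$replicates
  class(boot) <- "multiPhylo"
  boot_p <- file.path(config$dir, "backbone_boot.nwk")
  ape::write.tree(boot, boot_p)
  write_manifest(config, "bbinfer", c(fasta_p, part_p), c(bb_p, boot_p))
  invisible(c(bb_p, boot_p))
}

stage_bbdate <- function(config) {
  bb_p <- need_artifact(config, "backbone.nwk", "bbinfer")
  fos_p <- need_artifact(config, "fossils.tsv", "replicate")
  backbone <- read_tree(bb_p)
  fossils <- read_fossil_table(fos_p)
  dated <- date_tree(backbone$phy, calibrations = fossils,
                     outgroup = config$outgroup, partial = TRUE)
  # carry bootstrap support over to the rooted, dated topology
  if (nrow(backbone$data)) {
    src <- node_split_keys(backbone$phy)
    sup <- stats::setNames(backbone$data$support,
                           src[as.character(backbone$data$node)])
    dst <- node_split_keys(dated$phy)
    for (nd in names(dst)) {
      s <- sup[dst[[nd]]]
      if (!is.na(s)) dated <- set_anno(dated, as.integer(nd), support = unname(s))
    }
  }
  boot_p <- file.path(config$dir, "backbone_boot.nwk")
  if (file.exists(boot_p) && config$nboot > 0) {
    sample <- ape::read.tree(boot_p)
    if (inherits(sample, "phylo")) sample <- list(sample)
    dated <- date_with_sample(dated, sample, fossils,
                              outgroup = config$outgroup, partial = TRUE)
  }
  out_p <- file.path(config$dir, "backbone_dated.nwk")
  write_tree(dated, out_p)
  write_manifest(config, "bbdate", c(bb_p, fos_p, boot_p), out_p)
  invisible(out_p)
}

stage_decompose <- function(config) {
  dated_p <- need_artifact(config, "backbone_dated.nwk", "bbdate")
  taxa <- read_taxa_table(need_artifact(config, "taxa.tsv", "replicate"))
  in_dir <- alignment_input_dir(config)
  alignments <- read_alignment_dir(in_dir)
  dated <- read_tree(dated_p)
  consensus <- collapse_weak_splits(dated, config$consensus_threshold)
  mono <- assess_monophyly(consensus, taxa)
  tasks <- build_clade_tasks(consensus, dated, taxa, alignments,
                             max_clade_size = config$max_clade_size)
  dir <- config$dir
  mono_p <- file.path(dir, "monophyly.tsv")
  utils::write.table(mono, mono_p, sep = "\t", quote = FALSE, row.names = FALSE)
  tasks_p <- file.path(dir, "tasks.json")
  jsonlite::write_json(tasks, tasks_p, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  tsv <- do.call(rbind, lapply(tasks, function(t) data.frame(
    task_id = t$task_id, genera = paste(t$genera, collapse = ","),
    n_species = length(t$species),
    exemplars = paste(t$exemplars, collapse = ","),
    calibration_age = t$calibration_age,
    hpd_min = if (is.null(t$hpd)) NA_real_ else t$hpd[1],
    hpd_max = if (is.null(t$hpd)) NA_real_ else t$hpd[2],
    alignments = paste(t$alignment_ids, collapse = ","))))
  tasks_tsv <- file.path(dir, "tasks.tsv")
  utils::write.table(tsv, tasks_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, "decompose",
                 c(dated_p, file.path(dir, "taxa.tsv")),
                 c(mono_p, tasks_p, tasks_tsv))
  invisible(c(mono_p, tasks_p, tasks_tsv))
}

read_tasks <- function(path) {
  tasks <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  lapply(tasks, function(t) {
    t$hpd <- if (is.null(t$hpd)) NULL else unlist(t$hpd)
    t
  })
}

task_file_id <- function(task_id) gsub("[^A-Za-z0-9_+-]", "_", task_id)

stage_cladeinfer <- function(config) {
  tasks <- read_tasks(need_artifact(config, "tasks.json", "decompose"))
  in_dir <- alignment_input_dir(config)
  alignments <- read_alignment_dir(in_dir)
  out_dir <- file.path(config$dir, "clade_trees")
  dir.create(out_dir, showWarnings = FALSE)
  outputs <- character()
  for (task in tasks) {
    tr <- infer_clade_tree(task, alignments, nboot = config$clade_nboot,
                           seed = config$seed, model = config$model)
    if (is.null(tr)) next
    p <- file.path(out_dir, paste0(task_file_id(task$task_id), ".nwk"))
    write_tree(tr, p)
    outputs <- c(outputs, p)
  }
  write_manifest(config, "cladeinfer",
                 file.path(config$dir, "tasks.json"), outputs)
  invisible(outputs)
}

stage_graft <- function(config) {
  tasks <- read_tasks(need_artifact(config, "tasks.json", "decompose"))
  dated <- read_tree(need_artifact(config, "backbone_dated.nwk", "bbdate"))
  tree_dir <- need_artifact(config, "clade_trees", "cladeinfer")
  subtrees <- lapply(tasks, function(task) {
    p <- file.path(tree_dir, paste0(task_file_id(task$task_id), ".nwk"))
    if (!file.exists(p)) return(NULL)
    age <- task$calibration_age
    if (is.null(age) || !is.finite(age) || age <= 0) return(NULL)
    rescale_subtree(read_tree(p), task)
  })
  final <- graft_all(dated, subtrees, tasks, mode = config$graft_mode)
  out_p <- file.path(config$dir, "final.nwk")
  write_tree(final, out_p)
  write_manifest(config, "graft",
                 c(file.path(config$dir, "tasks.json"),
                   file.path(config$dir, "backbone_dated.nwk"),
                   list.files(tree_dir, full.names = TRUE)), out_p)
  invisible(out_p)
}

stage_treedist <- function(config) {
  td <- config$treedist
  if (is.null(td$tree1) || is.null(td$tree2))
    stop("config$treedist must name tree1 and tree2")
  res <- tree_distances(read_tree(td$tree1), read_tree(td$tree2),
                        denominator = td$denominator %||% "union")
  p <- file.path(config$dir, "treedist.tsv")
  utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "treedist", c(td$tree1, td$tree2), p)
  invisible(p)
}

stage_dispersal <- function(config) {
  dp <- config$dispersal
  if (is.null(dp$tree)) stop("config$dispersal must name an annotated tree")
  tr <- read_tree(dp$tree)
  events <- infer_dispersal_events(tr, per_source = isTRUE(dp$per_source))
  bins <- bin_dispersals(events, tr, bin_width = config$bin_width)
  p1 <- file.path(config$dir, "dispersal_events.tsv")
  p2 <- file.path(config$dir, "dispersal_bins.tsv")
  utils::write.table(events, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bins$series, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, "dispersal", dp$tree, c(p1, p2))
  invisible(c(p1, p2))
}

#' Run an external aligner via a command template
#'
#' Adapter hook for external multiple-sequence aligners: `{in}` and
#' `{out}` tokens in the template are replaced by the input/output FASTA
#' paths.  The returned alignment must contain exactly the input
#' sequences.
#'
#' @param cluster an unaligned [seq_cluster()].
#' @param cmd_template shell command with `{in}`/`{out}` tokens, e.g.
#'   `"mafft --auto {in} > {out}"`.
#' @return the aligned `seq_cluster`.
#' @export
run_aligner_adapter <- function(cluster, cmd_template) {
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta_cluster(cluster, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, cmd_template, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0) stop("aligner command failed: ", cmd)
  out <- read_fasta_cluster(fout, cluster_id = cluster$cluster_id,
                            seed_id = cluster$seed_id)
  if (!setequal(out$seq_id, cluster$seq_id))
    stop("aligner returned different sequences than were submitted")
  out$aligned <- TRUE
  out
}
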