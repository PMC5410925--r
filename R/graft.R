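#' Assess monophyly of genera on a backbone tree
#'
#' A genus (represented by its exemplar tips) is monophyletic when the
#' MRCA of its exemplars subtends only tips of that genus; genera with a
#' single tip are trivially monophyletic.
#'
#' @param backbone rooted tree (`phylo` or `chronogram`) whose tips are
#'   exemplar species.
#' @param taxa_table see [read_taxa_table()].
#' @return data frame: `genus`, `n_tips`, `monophyletic`.
#' @export
assess_monophyly <- function(backbone, taxa_table) {
  phy <- as_phylo(backbone)
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  unknown <- setdiff(phy$tip.label, names(genus_of))
  if (length(unknown))
    stop("backbone tips missing from taxa table: ", paste(unknown, collapse = ", "))
  tip_genus <- genus_of[phy$tip.label]
  out <- lapply(sort(unique(tip_genus)), function(g) {
    tips <- phy$tip.label[tip_genus == g]
    mono <- if (length(tips) < 2) TRUE else {
      node <- ape::getMRCA(phy, tips)
      clade <- ape::extract.clade(phy, node)$tip.label
      all(genus_of[clade] == g)
    }
    data.frame(genus = g, n_tips = length(tips), monophyletic = mono)
  })
  do.call(rbind, out)
}

#' Decompose a backbone into clade-level tasks
#'
#' Every genus starts as its own group; any group whose exemplars' MRCA
#' clade in the consensus backbone also subtends tips of other genera is
#' merged with those genera, iterated to a fixed point (union-find
#' semantics).  Monophyletic genera thus stay alone; interdigitated
#' genera merge into a joint task.  Each task is calibrated with the
#' dated-backbone age (and HPD, when annotated) of the MRCA of all its
#' exemplars, and receives every alignment holding at least two of its
#' species.
#'
#' @param consensus rooted consensus backbone (`phylo`).
#' @param dated_backbone dated backbone [chronogram()] sharing the
#'   consensus topology.
#' @param taxa_table see [read_taxa_table()].
#' @param alignments named list of aligned matrices (full species set).
#' @param max_clade_size warn when a task exceeds this many species.
#' @return list of clade tasks, each a list with `task_id`, `genera`,
#'   `species`, `exemplars`, `calibration_age`, `hpd`, `alignment_ids`.
#' @export
build_clade_tasks <- function(consensus, dated_backbone, taxa_table,
                              alignments, max_clade_size = 100L) {
  phy <- as_phylo(consensus)
  dated <- as_chronogram(dated_backbone)
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  tip_genus <- genus_of[phy$tip.label]
  genera <- sort(unique(tip_genus))
  groups <- as.list(genera)
  repeat {
    changed <- FALSE
    for (i in seq_along(groups)) {
      tips <- phy$tip.label[tip_genus %in% groups[[i]]]
      clade <- if (length(tips) < 2) tips else
        ape::extract.clade(phy, ape::getMRCA(phy, tips))$tip.label
      extra <- setdiff(unique(genus_of[clade]), groups[[i]])
      if (length(extra)) {
        hit <- which(vapply(groups, function(g) any(extra %in% g), FALSE))
        merged <- sort(unique(unlist(groups[c(i, hit)])))
        groups <- c(groups[-sort(unique(c(i, hit)))], list(merged))
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  if (length(groups) == 1L && length(genera) > 1L)
    warning("genus merging escalated to the backbone root: a single task remains")
  dated_ages <- node_ages(dated)
  tasks <- list()
  for (g in groups[order(vapply(groups, `[`, "", 1L))]) {
    species <- sort(taxa_table$species_id[taxa_table$genus %in% g])
    if (length(species) < 2) next
    exemplars <- sort(phy$tip.label[tip_genus %in% g])
    calib_age <- NA_real_; hpd <- NULL
    if (length(exemplars) >= 2) {
      node <- ape::getMRCA(dated$phy, exemplars)
      calib_age <- dated_ages[node]
      a <- anno_lookup(dated, node)
      if (!is.null(a) && !is.na(a$hpd_min)) hpd <- c(a$hpd_min, a$hpd_max)
    }
    aln_ids <- names(alignments)[vapply(alignments, function(m)
      sum(rownames(m) %in% species) >= 2, FALSE)]
    if (length(species) > max_clade_size)
      warning("task for ", paste(g, collapse = "+"), " holds ",
              length(species), " species (> max_clade_size); proceeding")
    tasks[[length(tasks) + 1L]] <- list(
      task_id = paste(g, collapse = "+"),
      genera = g, species = species, exemplars = exemplars,
      calibration_age = calib_age, hpd = hpd, alignment_ids = aln_ids)
  }
  tasks
}

# mean pairwise distance matrix across several alignments
mean_distance_matrix <- function(alignments, species, model = "JC69") {
  n <- length(species)
  acc <- matrix(0, n, n, dimnames = list(species, species))
  cnt <- matrix(0, n, n, dimnames = list(species, species))
  for (m in alignments) {
    sp <- intersect(species, rownames(m))
    if (length(sp) < 2) next
    d <- alignment_distances(m[sp, , drop = FALSE], model)
    ok <- is.finite(d)
    acc[sp, sp][ok] <- acc[sp, sp][ok] + d[ok]
    cnt[sp, sp][ok] <- cnt[sp, sp][ok] + ok[ok]
  }
  out <- acc / cnt
  diag(out) <- 0
  if (any(!is.finite(out))) {
    fin <- out[is.finite(out) & out > 0]
    if (!length(fin)) stop("no usable pairwise distances among task species")
    out[!is.finite(out)] <- 1.1 * max(fin)
  }
  out
}

#' Infer a relative-time ultrametric clade tree
#'
#' Distance stand-in for a coalescent clade analysis: NJ on the mean of
#' the per-alignment pairwise distances, midpoint-rooted, made
#' ultrametric by mean-path-length smoothing, and scaled so the root
#' sits at relative age 1.  With `nboot > 0`, alignment columns are
#' bootstrap-resampled and the 2.5/97.5% quantiles of each clade's
#' relative age become its HPD.
#'
#' @param task a clade task from [build_clade_tasks()].
#' @param alignments named list of aligned matrices.
#' @param nboot bootstrap replicates for node-age HPDs (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @param model distance model.
#' @return a [chronogram()] with root at relative age 1, or `NULL` when
#'   fewer than 3 task species have sequence data (the task then passes
#'   through as backbone-only).
#' @export
infer_clade_tree <- function(task, alignments, nboot = 0L, seed = 1L,
                             model = "JC69") {
  alns <- alignments[task$alignment_ids]
  species <- sort(intersect(task$species,
                            unique(unlist(lapply(alns, rownames)))))
  if (length(species) < 3) return(NULL)
  build <- function(alns) {
    d <- mean_distance_matrix(alns, species, model)
    phy <- ape::nj(stats::as.dist(d))
    phy$edge.length[phy$edge.length < 0] <- 0
    phy <- phangorn::midpoint(phy)
    ages <- mpl_ages(phy)
    if (max(ages) <= 0) stop("degenerate clade tree: zero depth")
    ages_to_chronogram(phy, ages / max(ages))
  }
  chron <- build(alns)
  if (nboot > 0) {
    reps <- with_seed(seed, lapply(seq_len(nboot), function(i) {
      res <- lapply(alns, function(m) m[, sample.int(ncol(m), ncol(m),
                                                     replace = TRUE),
                                       drop = FALSE])
      tryCatch(build(res), error = function(e) NULL)
    }))
    reps <- Filter(Negate(is.null), reps)
    ages_by_key <- list()
    for (r in reps) {
      keys <- clade_keys(r$phy); ages <- node_ages(r)
      for (i in seq_along(keys))
        ages_by_key[[keys[i]]] <- c(ages_by_key[[keys[i]]],
                                    ages[as.integer(names(keys)[i])])
    }
    main_keys <- clade_keys(chron$phy); main_ages <- node_ages(chron)
    for (i in seq_along(main_keys)) {
      obs <- ages_by_key[[main_keys[i]]]
      if (length(obs) >= 2) {
        nd <- as.integer(names(main_keys)[i])
        q <- stats::quantile(obs, c(0.025, 0.975), names = FALSE)
        chron <- set_anno(chron, nd,
                          hpd_min = min(q[1], main_ages[nd]),
                          hpd_max = max(q[2], main_ages[nd]))
      }
    }
  }
  chron
}

#' Rescale a clade subtree to its backbone calibration age
#'
#' Every branch length and every HPD bound is multiplied by the single
#' factor `f = calibration_age / (relative age of the exemplars' MRCA in
#' the subtree)`, after which the exemplar MRCA sits exactly at the
#' backbone age.
#'
#' @param subtree relative-time ultrametric [chronogram()] containing
#'   both exemplars as tips.
#' @param task clade task providing `exemplars` and `calibration_age`.
#' @return the rescaled `chronogram`, with attribute `"scale_factor"`.
#' @export
rescale_subtree <- function(subtree, task) {
  chron <- as_chronogram(subtree)
  ex <- task$exemplars
  if (!all(ex %in% chron$phy$tip.label))
    stop("exemplars not all tips of the subtree")
  if (length(ex) < 2) stop("need two exemplars to rescale")
  node <- ape::getMRCA(chron$phy, ex)
  rel <- node_ages(chron)[node]
  if (rel <= 0) stop("exemplar MRCA at age 0: cannot rescale")
  if (is.na(task$calibration_age) || task$calibration_age <= 0)
    stop("task has no positive calibration age")
  f <- task$calibration_age / rel
  chron$phy$edge.length <- chron$phy$edge.length * f
  chron$data$hpd_min <- chron$data$hpd_min * f
  chron$data$hpd_max <- chron$data$hpd_max * f
  attr(chron, "scale_factor") <- f
  chron
}

#' Graft one rescaled clade subtree onto the backbone
#'
#' The backbone clade at the exemplars' MRCA is replaced by the subtree.
#' When the subtree root coincides with the exemplar MRCA (exemplars
#' span the subtree root) the stem branch is untouched; otherwise the
#' excess depth `d = (subtree root age) - (backbone exemplar-MRCA age)`
#' is subtracted from the stem branch leading to the clade.  If `d`
#' meets or exceeds the stem length the graft would create a negative
#' branch: the default is a hard error naming the clade; `mode =
#' "clamp"` instead re-rescales the subtree so its root sits `epsilon`
#' below the backbone parent node, with a loud diagnostic (the exemplar
#' MRCA then no longer matches the backbone age exactly).
#'
#' @param backbone dated backbone [chronogram()].
#' @param subtree rescaled clade [chronogram()] (see
#'   [rescale_subtree()]).
#' @param task the clade task.
#' @param mode `"error"` (default) or `"clamp"`.
#' @param epsilon age gap used in clamp mode, Ma.
#' @param tol age tolerance for treating root and MRCA as coincident.
#' @return the grafted [chronogram()].
#' @export
graft_subtree <- function(backbone, subtree, task,
                          mode = c("error", "clamp"), epsilon = 1e-6,
                          tol = 1e-9) {
  mode <- match.arg(mode)
  backbone <- as_chronogram(backbone)
  subtree <- as_chronogram(subtree)
  ex <- task$exemplars
  if (!all(ex %in% backbone$phy$tip.label))
    stop("exemplar pair not present in backbone for task ", task$task_id)
  bb <- chron_to_nested(backbone)
  sub_root <- chron_to_nested(subtree)
  mrca <- nested_find_mrca(bb, ex)
  age_b <- mrca$age
  target_tips <- nested_tips(mrca)
  R <- sub_root$age
  d <- R - age_b
  if (d < -tol)
    stop("subtree root (", R, ") younger than backbone exemplar MRCA (",
         age_b, "): was the subtree rescaled?")
  is_root <- setequal(target_tips, nested_tips(bb))
  if (d > tol) {
    if (is_root)
      stop("negative branch: subtree for task ", task$task_id,
           " is deeper than the backbone root and has no stem to shorten")
    # find the stem: parent of the mrca clade
    parent_age <- nested_parent_age(bb, target_tips)
    stem <- parent_age - age_b
    if (d >= stem - tol) {
      if (mode == "error")
        stop("negative branch: grafting task ", task$task_id,
             " needs d = ", format(d), " but the stem is only ", format(stem))
      g <- (parent_age - epsilon) / R
      warning("task ", task$task_id, ": subtree clamped by factor ",
              format(g), " to avoid a negative stem branch; its exemplar",
              " MRCA no longer matches the backbone age exactly")
      sub_root <- scale_nested(sub_root, g)
      R <- sub_root$age
    }
  }
  if (is_root) {
    out <- sub_root
  } else {
    out <- replace_nested_clade(bb, target_tips, sub_root)
  }
  res <- nested_to_chron(out)
  validate_chronogram(res)
  res
}

nested_parent_age <- function(root, target_tips) {
  find <- function(node) {
    for (ch in node$children) {
      if (setequal(nested_tips(ch), target_tips)) return(node$age)
      if (all(target_tips %in% nested_tips(ch))) return(find(ch))
    }
    stop("clade not found in backbone")
  }
  find(root)
}

replace_nested_clade <- function(node, target_tips, replacement) {
  for (i in seq_along(node$children)) {
    ch <- node$children[[i]]
    if (setequal(nested_tips(ch), target_tips)) {
      node$children[[i]] <- replacement
      return(node)
    }
    if (all(target_tips %in% nested_tips(ch)))
      node$children[[i]] <- replace_nested_clade(ch, target_tips, replacement)
  }
  node
}

scale_nested <- function(node, f) {
  node$age <- node$age * f
  if (!is.null(node$hpd)) node$hpd <- node$hpd * f
  node$children <- lapply(node$children, scale_nested, f = f)
  node
}

#' Graft all clade subtrees onto the backbone
#'
#' Grafts are applied in descending order of backbone calibration age
#' (deepest clades first).  Tasks without a subtree (too little data)
#' pass through: their exemplars stay in place.  Any failing graft
#' aborts with a per-clade report; the partial result up to the failure
#' is attached to the error condition.
#'
#' @param backbone dated backbone [chronogram()].
#' @param subtrees list of rescaled clade chronograms (may contain
#'   `NULL`s), parallel to `tasks`.
#' @param tasks list of clade tasks.
#' @param mode negative-branch handling, see [graft_subtree()].
#' @return the final species-level [chronogram()].
#' @export
graft_all <- function(backbone, subtrees, tasks, mode = "error") {
  stopifnot(length(subtrees) == length(tasks))
  keep <- !vapply(subtrees, is.null, TRUE)
  subtrees <- subtrees[keep]; tasks <- tasks[keep]
  if (!length(tasks)) return(as_chronogram(backbone))
  ord <- order(-vapply(tasks, `[[`, 0, "calibration_age"),
               vapply(tasks, `[[`, "", "task_id"))
  current <- as_chronogram(backbone)
  for (i in ord) {
    current <- tryCatch(
      graft_subtree(current, subtrees[[i]], tasks[[i]], mode = mode),
      error = function(e) {
        cond <- simpleError(paste0("graft failed for task ",
                                   tasks[[i]]$task_id, ": ",
                                   conditionMessage(e)))
        cond$partial <- current
        stop(cond)
      })
  }
  validate_chronogram(current)
  current
}
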