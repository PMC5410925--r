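# Log-likelihood of branching times under the conditioned constant-rate
# birth-death process, parameterized by net diversification r = lambda - mu
# and turnover a = mu / lambda (Nee et al.'s reconstructed-process form).
bd_loglik <- function(r, a, bt) {
  N <- length(bt) + 1L              # tips
  bt <- sort(bt, decreasing = TRUE) # bt[1] = root age
  z <- r * bt
  # log(exp(z) - a), overflow-safe
  lg <- z + log1p(-a * exp(-z))
  lfactorial(N - 1) + (N - 2) * log(r) + r * sum(bt[-1]) +
    N * log(1 - a) - 2 * sum(lg)
}

#' Maximum-likelihood fit of a constant-rate birth-death model
#'
#' Maximizes the reconstructed-process likelihood of the branching times
#' over net diversification `r = lambda - mu` and turnover
#' `a = mu / lambda`, with `a` bounded in `[0, 1 - 1e-6]`, and reports
#' the implied per-lineage rates.
#'
#' @param tree an ultrametric tree (`chronogram` or `phylo`) with at
#'   least 3 tips.
#' @return list: `lambda`, `mu`, `r`, `epsilon` (turnover), `loglik`.
#' @export
fit_birth_death <- function(tree) {
  phy <- as_phylo(tree)
  bt <- unname(ape::branching.times(phy))
  if (length(bt) < 2) stop("need at least 2 branching times")
  obj <- function(p) {
    r <- exp(p[1]); a <- stats::plogis(p[2]) * (1 - 1e-6)
    -bd_loglik(r, a, bt)
  }
  start <- c(log(max(log(ape::Ntip(phy) / 2) / max(bt), 1e-3)), stats::qlogis(0.2))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  r <- exp(fit$par[1]); a <- stats::plogis(fit$par[2]) * (1 - 1e-6)
  # polish near the a = 0 boundary: Yule-like data often sit there
  fit0 <- stats::optimize(function(r) -bd_loglik(r, 0, bt),
                          interval = c(1e-8, 10 * r))
  if (fit0$objective < fit$value) {
    r <- fit0$minimum; a <- 0
    fit$value <- fit0$objective
  }
  lambda <- r / (1 - a)
  list(lambda = lambda, mu = a * lambda, r = r, epsilon = a,
       loglik = -fit$value)
}

#' Simulate a birth-death tree conditioned on its number of extant tips
#'
#' Forward (Gillespie) simulation from two crown lineages: each extant
#' lineage speciates at rate `lambda` and goes extinct at rate `mu`.
#' The simulation stops the first time the extant count reaches
#' `n_tips`, extended by the waiting time to the event that would change
#' the count; runs in which the process dies out are rejected and
#' restarted.  Extinct lineages are pruned, so the returned tree is
#' ultrametric with exactly `n_tips` tips (labelled `s001`, `s002`, ...).
#'
#' @param lambda,mu speciation and extinction rates (per lineage per Ma,
#'   `lambda > mu >= 0`).
#' @param n_tips number of extant tips (>= 2).
#' @param seed RNG seed; the same seed yields the identical tree.
#' @param max_tries rejection budget before giving up.
#' @return an ultrametric [chronogram()].
#' @export
simulate_bd_tree <- function(lambda, mu, n_tips, seed = 1L,
                             max_tries = 1000L) {
  stopifnot(n_tips >= 2, lambda > mu, mu >= 0)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      res <- sim_bd_once(lambda, mu, n_tips)
      if (!is.null(res)) return(res)
    }
    stop("rejection budget exhausted: mu too close to lambda?")
  })
}

sim_bd_once <- function(lambda, mu, n) {
  # nodes: birth, death (NA = alive), children (integer pair or NULL)
  birth <- c(0, 0); death <- c(NA_real_, NA_real_)
  kids <- list(NULL, NULL)
  active <- c(1L, 2L)
  t <- 0
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    tau <- stats::rexp(1, k * (lambda + mu))
    if (k == n) { t_end <- t + tau; break }
    t <- t + tau
    i <- active[sample.int(k, 1L)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      id1 <- length(birth) + 1L; id2 <- id1 + 1L
      birth <- c(birth, t, t); death <- c(death, NA, NA)
      kids <- c(kids, list(NULL, NULL))
      kids[[i]] <- c(id1, id2)
      death[i] <- t
      active <- c(setdiff(active, i), id1, id2)
    } else {
      death[i] <- t
      active <- setdiff(active, i)
    }
  }
  tipctr <- 0L
  nwk <- function(i) {
    end <- if (is.na(death[i])) t_end else death[i]
    len <- end - birth[i]
    if (is.null(kids[[i]])) {
      lab <- if (is.na(death[i])) {
        tipctr <<- tipctr + 1L
        sprintf("s%03d", tipctr)
      } else sprintf("x%d", i)
      paste0(lab, ":", format_num(len, 12))
    } else {
      paste0("(", nwk(kids[[i]][1]), ",", nwk(kids[[i]][2]), "):",
             format_num(len, 12))
    }
  }
  phy <- ape::read.tree(text = paste0("(", nwk(1L), ",", nwk(2L), ");"))
  extinct <- grep("^x", phy$tip.label, value = TRUE)
  if (length(extinct)) phy <- ape::drop.tip(phy, extinct)
  if (ape::Ntip(phy) != n) return(NULL)
  chronogram(phy)
}

#' Assign simulated tips to monophyletic genera mirroring a reference
#'
#' Works through the reference genera in descending size; for each, the
#' still-unused clade of the simulated tree whose tip count is closest
#' to the target size is chosen (ties: crown age closest to the
#' reference crown age, then random under `seed`).  Chosen clades are
#' disjoint, so all genera are monophyletic by construction; when no
#' clade of adequate size remains the best available smaller clade is
#' used and reported.  Tips left unassigned become monotypic genera.
#'
#' @param sim_tree simulated [chronogram()].
#' @param profile data frame `genus`, `size`, `crown_age` (Ma; 0 or NA
#'   for monotypic genera); `sum(size)` must not exceed the tip count.
#' @param seed RNG seed for random tie-breaks.
#' @return list: `genus_map` (named character vector, tip -> genus) and
#'   `report` (per-genus target vs achieved size and crown age).
#' @export
assign_genera <- function(sim_tree, profile, seed = 1L) {
  chron <- as_chronogram(sim_tree)
  phy <- chron$phy
  ntip <- ape::Ntip(phy)
  if (sum(profile$size) > ntip)
    stop("profile sizes exceed the number of simulated tips")
  ages <- node_ages(chron)
  # candidate clades: every internal node plus every single tip
  keys <- clade_keys(phy)
  cand <- data.frame(node = c(seq_len(ntip), as.integer(names(keys))),
                     size = c(rep(1L, ntip),
                              lengths(strsplit(unname(keys), ";", fixed = TRUE))),
                     age = c(rep(0, ntip), ages[as.integer(names(keys))]))
  cand_tips <- c(as.list(phy$tip.label),
                 lapply(strsplit(unname(keys), ";", fixed = TRUE), identity))
  used <- character()
  genus_map <- character(); report <- list()
  prof <- profile[order(-profile$size, profile$genus), ]
  with_seed(seed, {
    for (i in seq_len(nrow(prof))) {
      free <- which(vapply(cand_tips, function(tp) !any(tp %in% used), TRUE))
      if (!length(free)) stop("no free clade left for genus ", prof$genus[i])
      sz <- cand$size[free]
      target <- prof$size[i]
      # prefer exact/closest size; when nothing <= target exists this still
      # returns the closest available clade
      dd <- abs(sz - target)
      best <- free[dd == min(dd)]
      if (length(best) > 1) {
        ta <- prof$crown_age[i]
        if (!is.na(ta)) {
          da <- abs(cand$age[best] - ta)
          best <- best[da == min(da)]
        }
        if (length(best) > 1) best <- best[sample.int(length(best), 1L)]
      }
      tips <- cand_tips[[best]]
      used <- c(used, tips)
      genus_map[tips] <- prof$genus[i]
      report[[i]] <- data.frame(
        genus = prof$genus[i], target_size = target,
        achieved_size = length(tips),
        target_age = prof$crown_age[i], achieved_age = cand$age[best],
        split = length(tips) < target)
    }
  })
  leftovers <- setdiff(phy$tip.label, names(genus_map))
  if (length(leftovers))
    genus_map[leftovers] <- paste0("mono_", leftovers)
  list(genus_map = genus_map[phy$tip.label],
       report = do.call(rbind, report))
}

#' Fit a substitution model to an alignment
#'
#' Candidate models `{JC, K80, HKY, GTR} x {+Gamma(4), none}` are scored
#' by maximum likelihood on a fixed NJ guide topology with optimized
#' branch lengths; the winner is chosen by AIC, with ties going to the
#' simpler model (candidates are evaluated simple to complex).
#'
#' @param mat aligned character matrix (>= 3 rows, >= 1 variable site).
#' @param models candidate model names (phangorn spelling).
#' @param try_gamma also try each model with 4-category Gamma rates.
#' @return list: `model`, `gamma`, `bf` (ACGT), `Q` (six exchangeabilities
#'   AC, AG, AT, CG, CT, GT), `shape` (`NA` without Gamma), `length`,
#'   `rate` (clock scaling, 1 until set by the replicator), `loglik`,
#'   `aic`, `aic_table`.
#' @export
fit_subst_model <- function(mat, models = c("JC", "K80", "HKY", "GTR"),
                            try_gamma = TRUE) {
  if (nrow(mat) < 3) stop("need >= 3 sequences")
  variable <- any(apply(mat, 2, function(col) {
    r <- unique(col[col %in% c("A", "C", "G", "T")])
    length(r) > 1
  }))
  if (!variable) stop("all sites invariable")
  pd <- phangorn::phyDat(mat, type = "DNA")
  guide <- suppressWarnings(nj_tree(mat))
  guide$edge.length[guide$edge.length <= 0] <- 1e-8
  grid <- expand.grid(gamma = if (try_gamma) c(FALSE, TRUE) else FALSE,
                      model = models, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$model, models), grid$gamma), ]
  fits <- vector("list", nrow(grid)); aics <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- if (grid$gamma[i]) 4L else 1L
    base <- phangorn::pml(guide, pd, k = k, shape = if (k > 1) 0.5 else 1)
    fit <- suppressWarnings(phangorn::optim.pml(
      base, model = grid$model[i], optGamma = grid$gamma[i],
      optEdge = TRUE, control = phangorn::pml.control(trace = 0)))
    fits[[i]] <- fit
    aics[i] <- stats::AIC(fit)
  }
  best <- which.min(aics)           # first minimum = simplest on ties
  fit <- fits[[best]]
  list(model = grid$model[best], gamma = grid$gamma[best],
       bf = fit$bf, Q = fit$Q,
       shape = if (grid$gamma[best]) fit$shape else NA_real_,
       length = ncol(mat), rate = 1,
       loglik = as.numeric(stats::logLik(fit)), aic = aics[best],
       aic_table = data.frame(model = grid$model, gamma = grid$gamma,
                              aic = aics))
}

#' Simulate an aligned sequence cluster along a tree
#'
#' The root sequence is drawn from the model's base frequencies and
#' evolved along the tree under the continuous-time substitution model
#' in `spec` (`Q`, `bf`, optional 4-category discrete-Gamma site rates),
#' with branch lengths in Ma multiplied by `spec$rate` (substitutions
#' per site per Ma).  An optional simple indel process (deletions at a
#' constant per-branch rate with geometric lengths) is off by default.
#'
#' @param tree dated tree (`chronogram` or `phylo`).
#' @param spec model spec, see [fit_subst_model()]; `spec$length` sites.
#' @param species_subset tips to include (the cluster's occupancy row).
#' @param seed RNG seed.
#' @param indel_rate expected deletion events per unit branch length
#'   (default 0 = off).
#' @param indel_mean_len mean deletion length (geometric).
#' @return aligned character matrix, rows = `species_subset`.
#' @export
simulate_alignment <- function(tree, spec, species_subset, seed = 1L,
                               indel_rate = 0, indel_mean_len = 3) {
  phy <- as_phylo(tree)
  if (!length(species_subset)) stop("empty species subset")
  missing <- setdiff(species_subset, phy$tip.label)
  if (length(missing)) stop("subset tips not in tree: ",
                            paste(missing, collapse = ", "))
  phy <- ape::keep.tip(phy, species_subset)
  phy$edge.length <- phy$edge.length * (spec$rate %||% 1)
  l <- spec$length
  with_seed(seed, {
    if (!is.null(spec$shape) && !is.na(spec$shape)) {
      g <- phangorn::discrete.gamma(spec$shape, k = 4)
      cat_of <- sample.int(4, l, replace = TRUE)
    } else {
      g <- 1; cat_of <- rep(1L, l)
    }
    out <- matrix(NA_character_, length(species_subset), l,
                  dimnames = list(species_subset, NULL))
    for (k in seq_along(g)) {
      idx <- which(cat_of == k)
      if (!length(idx)) next
      ph <- phy; ph$edge.length <- ph$edge.length * g[k]
      sim <- phangorn::simSeq(ph, l = length(idx), Q = spec$Q, bf = spec$bf,
                              type = "DNA")
      m <- toupper(as.character(sim))
      out[, idx] <- m[species_subset, , drop = FALSE]
    }
    if (indel_rate > 0) {
      total <- sum(phy$edge.length)
      n_events <- stats::rpois(1, indel_rate * total)
      if (n_events > 0) {
        eprob <- phy$edge.length / total
        for (ev in seq_len(n_events)) {
          e <- sample.int(nrow(phy$edge), 1, prob = eprob)
          below <- phangorn::Descendants(phy, phy$edge[e, 2], "tips")[[1]]
          start <- sample.int(l, 1)
          len <- stats::rgeom(1, 1 / indel_mean_len) + 1L
          cols <- start:min(l, start + len - 1L)
          out[phy$tip.label[below], cols] <- "-"
        }
      }
    }
    out
  })
}

is_variable_alignment <- function(mat) {
  any(apply(mat, 2, function(col) {
    r <- unique(col[col %in% c("A", "C", "G", "T")])
    length(r) > 1
  }))
}

genus_profile <- function(tree, taxa_table) {
  chron <- as_chronogram(tree)
  ages <- node_ages(chron)
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  tips <- chron$phy$tip.label
  out <- lapply(sort(unique(genus_of[tips])), function(g) {
    members <- tips[genus_of[tips] == g]
    age <- if (length(members) < 2) 0 else
      ages[ape::getMRCA(chron$phy, members)]
    data.frame(genus = g, size = length(members), crown_age = age)
  })
  do.call(rbind, out)
}

# mean tip-to-tip path time (2 x pairwise MRCA age) among given tips
mean_path_time <- function(tree, tips) {
  chron <- as_chronogram(tree)
  if (length(tips) < 2) return(NA_real_)
  dm <- ape::cophenetic.phylo(ape::keep.tip(chron$phy, tips))
  mean(dm[upper.tri(dm)])
}

#' Replicate a reference dataset by simulation
#'
#' Fits a birth-death model to the reference tree, simulates a tree of
#' the same size, assigns its tips to genera mirroring the reference
#' genus size/age profile, and re-simulates every reference cluster on
#' the new tree: the substitution model is fitted to the reference
#' cluster, the reference species are mapped to simulated species by a
#' genus-preserving bijection, the clock rate is chosen so the simulated
#' cluster matches the reference cluster's mean divergence, and the
#' cluster's occupancy row is carried over.  Invariable simulated
#' alignments are dropped, as they carry no signal and would only
#' inflate the marker count.
#'
#' @param reference list with `tree` (dated [chronogram()]), `clusters`
#'   (named list of aligned character matrices, rows = species ids) and
#'   `taxa` (taxa table).
#' @param seed master RNG seed.
#' @param models candidate substitution models (see
#'   [fit_subst_model()]).
#' @return list: `tree` (the new true chronogram), `taxa`, `genus_map`,
#'   `clusters` (simulated, named as the reference), `mapping`
#'   (reference species -> simulated species), `dropped_invariable`,
#'   `summary` (per-cluster length/divergence/occupancy, real vs
#'   simulated), `bd` (fitted birth-death parameters).
#' @export
replicate_dataset <- function(reference, seed = 1L,
                              models = c("JC", "K80", "HKY", "GTR")) {
  ref_tree <- as_chronogram(reference$tree)
  taxa <- validate_taxa_table(reference$taxa)
  bd <- fit_birth_death(ref_tree)
  n <- ape::Ntip(ref_tree$phy)
  sim_tree <- simulate_bd_tree(bd$lambda, bd$mu, n, seed = derive_seed(seed, 1))
  prof <- genus_profile(ref_tree, taxa)
  asg <- assign_genera(sim_tree, prof, seed = derive_seed(seed, 2))
  genus_of <- stats::setNames(taxa$genus, taxa$species_id)
  # genus-preserving species mapping, reference -> simulated
  mapping <- character()
  for (g in prof$genus) {
    ref_sp <- sort(ref_tree$phy$tip.label[genus_of[ref_tree$phy$tip.label] == g])
    sim_sp <- sort(names(asg$genus_map)[asg$genus_map == g])
    k <- min(length(ref_sp), length(sim_sp))
    if (k > 0) mapping[ref_sp[seq_len(k)]] <- sim_sp[seq_len(k)]
  }
  sim_taxa <- data.frame(species_id = names(asg$genus_map),
                         species_name = names(asg$genus_map),
                         genus = unname(asg$genus_map),
                         stringsAsFactors = FALSE)
  clusters <- list(); dropped <- character(); summ <- list()
  i <- 0L
  for (id in names(reference$clusters)) {
    i <- i + 1L
    ref_mat <- reference$clusters[[id]]
    spec <- fit_subst_model(ref_mat, models = models)
    occupants <- intersect(rownames(ref_mat), names(mapping))
    sim_sp <- unname(mapping[occupants])
    if (length(sim_sp) < 2) { dropped <- c(dropped, id); next }
    ref_div <- tryCatch(as.numeric(average_divergence(ref_mat)),
                        error = function(e) NA_real_)
    path <- mean_path_time(sim_tree, sim_sp)
    spec$rate <- if (is.finite(ref_div) && is.finite(path) && path > 0)
      max(ref_div / path, 1e-6) else 1e-3
    sim_mat <- simulate_alignment(sim_tree, spec, sim_sp,
                                  seed = derive_seed(seed, 10 + i))
    if (!is_variable_alignment(sim_mat)) { dropped <- c(dropped, id); next }
    clusters[[id]] <- sim_mat
    summ[[id]] <- data.frame(
      cluster = id, length_real = ncol(ref_mat), length_sim = ncol(sim_mat),
      divergence_real = ref_div,
      divergence_sim = tryCatch(as.numeric(average_divergence(sim_mat)),
                                error = function(e) NA_real_),
      occupancy_real = nrow(ref_mat), occupancy_sim = nrow(sim_mat))
  }
  list(tree = sim_tree, taxa = sim_taxa, genus_map = asg$genus_map,
       clusters = clusters, mapping = mapping,
       dropped_invariable = dropped,
       summary = do.call(rbind, summ), bd = bd,
       assignment_report = asg$report)
}
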