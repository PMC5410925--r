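#' Pairwise sequence distance between two aligned rows
#'
#' Sites where either row carries a gap, `?` or an IUPAC ambiguity code
#' are excluded (pairwise deletion).  Under JC69 the distance is
#' \eqn{-\frac{3}{4}\ln(1 - \frac{4}{3}p)} where `p` is the proportion of
#' differing comparable sites; `p >= 3/4` lies outside the model's domain
#' and returns `Inf` as a saturation sentinel.
#'
#' @param row_a,row_b equal-length aligned sequences (strings or
#'   character vectors).
#' @param model `"JC69"` (default) or `"p"` for the raw p-distance.
#' @return nonnegative distance (possibly `Inf`).
#' @export
pairwise_distance <- function(row_a, row_b, model = c("JC69", "p")) {
  model <- match.arg(model)
  a <- seq_chars(row_a); b <- seq_chars(row_b)
  if (length(a) != length(b)) stop("rows must have equal aligned length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) stop("zero comparable sites between rows")
  p <- sum(a[ok] != b[ok]) / n
  if (model == "p") return(p)
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

# Full pairwise distance matrix for an alignment (rows = species).
# NA marks pairs with zero comparable sites; Inf marks saturated pairs.
alignment_distances <- function(mat, model = "JC69") {
  n <- nrow(mat)
  valid <- matrix(mat %in% c("A", "C", "G", "T"), n)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    m <- sum(ok)
    if (m == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
    p <- sum(mat[i, ok] != mat[j, ok]) / m
    v <- if (model == "p") p
         else if (p >= 0.75) Inf
         else -0.75 * log(1 - 4 * p / 3)
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Filter species that share too few markers with other taxa
#'
#' A species is kept when it co-occurs with at least one congener in at
#' least `min_shared_intra` alignments AND with at least one species of
#' another genus in at least `min_shared_inter` alignments.  Species of
#' monotypic genera are exempt from the intrageneric rule (they have no
#' congeners to share with).
#'
#' @param alignments named list of aligned character matrices with
#'   species ids as rownames.
#' @param taxa_table see [read_taxa_table()].
#' @param min_shared_intra,min_shared_inter co-occurrence thresholds
#'   (defaults 1).
#' @return list with `retained` (character vector of species ids) and
#'   `excluded` (data frame `species_id`, `reason`).
#' @export
filter_sparse_taxa <- function(alignments, taxa_table,
                               min_shared_intra = 1L, min_shared_inter = 1L) {
  stopifnot(min_shared_intra >= 0L, min_shared_inter >= 0L)
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  genus_sizes <- table(taxa_table$genus)
  rows <- lapply(alignments, rownames)
  unknown <- setdiff(unique(unlist(rows)), names(genus_of))
  if (length(unknown))
    stop("species in alignments missing from taxa table: ",
         paste(unknown, collapse = ", "))
  retained <- character(); excl <- list()
  for (sp in taxa_table$species_id) {
    g <- genus_of[[sp]]
    intra <- sum(vapply(rows, function(r)
      sp %in% r && any(genus_of[setdiff(r, sp)] == g), FALSE))
    inter <- sum(vapply(rows, function(r)
      sp %in% r && any(genus_of[setdiff(r, sp)] != g), FALSE))
    intra_ok <- genus_sizes[[g]] == 1L || intra >= min_shared_intra
    inter_ok <- inter >= min_shared_inter
    if (intra_ok && inter_ok) retained <- c(retained, sp)
    else excl[[length(excl) + 1L]] <- data.frame(
      species_id = sp,
      reason = paste(c(if (!intra_ok) "too_few_intrageneric_markers",
                       if (!inter_ok) "too_few_intergeneric_markers"),
                     collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(retained = retained,
       excluded = if (length(excl)) do.call(rbind, excl) else
         data.frame(species_id = character(), reason = character()))
}

# sorted species pair -> canonical "x|y" key
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Select two exemplar species per genus by weighted distal-pair voting
#'
#' For every alignment holding `k >= 2` congeners of a genus, the pair
#' with the largest pairwise distance receives a vote of weight
#' `n - 1`, where `n = k(k-1)/2` is the number of within-genus pairwise
#' comparisons in that alignment.  Large alignments thus dominate: their
#' most distal pair is more likely to span the genus root.  The pair with
#' the highest accumulated weight becomes the genus' exemplars.  All ties
#' (equal distance within an alignment, equal final weight) are broken
#' lexicographically by species id, so the result does not depend on
#' input order.
#'
#' @param alignments named list of aligned matrices, one row per species.
#' @param taxa_table see [read_taxa_table()].
#' @param model distance model passed to the pairwise comparisons.
#' @return data frame with one row per genus that has sequenced species:
#'   `genus`, `exemplar_1`, `exemplar_2` (`NA` for single-species
#'   genera), `weight`, `n_votes` (number of alignments that voted).
#' @export
select_exemplars <- function(alignments, taxa_table, model = "JC69") {
  genus_of <- stats::setNames(taxa_table$genus, taxa_table$species_id)
  present <- sort(unique(unlist(lapply(alignments, rownames))))
  out <- list()
  for (g in sort(unique(taxa_table$genus))) {
    members <- sort(intersect(taxa_table$species_id[taxa_table$genus == g], present))
    if (!length(members)) { warning("genus ", g, " has no sequenced species; omitted"); next }
    if (length(members) == 1L) {
      out[[g]] <- data.frame(genus = g, exemplar_1 = members,
                             exemplar_2 = NA_character_,
                             weight = NA_real_, n_votes = 0L)
      next
    }
    if (length(members) == 2L) {
      # the pair is forced; its votes would all carry w = n - 1 = 0
      out[[g]] <- data.frame(genus = g, exemplar_1 = members[1],
                             exemplar_2 = members[2],
                             weight = 0, n_votes = 0L)
      next
    }
    tally <- numeric(); votes <- 0L
    for (aln in alignments) {
      sp <- sort(intersect(rownames(aln), members))
      k <- length(sp)
      if (k < 2L) next
      d <- alignment_distances(aln[sp, , drop = FALSE], model)
      d[is.na(d)] <- -Inf                 # incomparable pairs never win
      best <- NULL; best_d <- -Inf
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        if (d[i, j] > best_d) { best_d <- d[i, j]; best <- c(sp[i], sp[j]) }
      }
      if (is.null(best) || !is.finite(best_d) && best_d < 0) next
      w <- k * (k - 1) / 2 - 1
      key <- pair_key(best[1], best[2])
      tally[key] <- (if (key %in% names(tally)) tally[[key]] else 0) + w
      votes <- votes + 1L
    }
    if (!length(tally)) {
      # no alignment voted: fall back to the lexicographically smallest pair
      win <- members[1:2]; w <- 0
    } else {
      mx <- max(tally)
      win_key <- sort(names(tally)[tally == mx])[1]
      win <- strsplit(win_key, "|", fixed = TRUE)[[1]]
      w <- mx
    }
    out[[g]] <- data.frame(genus = g, exemplar_1 = win[1], exemplar_2 = win[2],
                           weight = w, n_votes = votes)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# flat vector of exemplar species ids
exemplar_species <- function(exemplars) {
  sort(unique(stats::na.omit(c(exemplars$exemplar_1, exemplars$exemplar_2))))
}
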