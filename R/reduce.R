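#' Reduce a cluster to a fixed number of sequences per species
#'
#' Clusters mined from public repositories are heavily biased toward
#' much-sequenced species.  For each species at most `keep` sequences are
#' retained, ranked by (1) fewest IUPAC ambiguity symbols, (2) smallest
#' deviation of the gap-free length from the species' median gap-free
#' length, (3) sequence id (lexicographic), in that order.  The aim is to
#' drop short fragments when fuller sequences exist, while also avoiding
#' over-long sequences likely to run into neighbouring markers.
#'
#' The operation is idempotent.  If the seed sequence loses its species'
#' ranking it is dropped like any other sequence, but its identity and
#' residues are remembered on the cluster for later seed-based merging.
#'
#' @param cluster a [seq_cluster()].
#' @param keep maximum sequences retained per species (default 1).
#' @return the reduced `seq_cluster`.
#' @export
reduce_cluster <- function(cluster, keep = 1L) {
  stopifnot(inherits(cluster, "seq_cluster"), keep >= 1L)
  amb <- vapply(cluster$seqs, count_ambiguities, 0L)
  len <- vapply(cluster$seqs, ungapped_length, 0L)
  keep_idx <- integer()
  for (sp in unique(cluster$species_id)) {
    idx <- which(cluster$species_id == sp)
    med <- stats::median(len[idx])
    ord <- idx[order(amb[idx], abs(len[idx] - med), cluster$seq_id[idx])]
    keep_idx <- c(keep_idx, ord[seq_len(min(keep, length(ord)))])
  }
  keep_idx <- sort(keep_idx)
  seq_cluster(cluster$cluster_id,
              cluster$seq_id[keep_idx], cluster$species_id[keep_idx],
              unname(cluster$seqs[keep_idx]),
              seed_id = cluster$seed_id, aligned = cluster$aligned,
              seed_seq = cluster$seed_seq)
}

#' k-mer Jaccard similarity between two sequences
#'
#' Used for the all-versus-all comparison of cluster seed sequences when
#' deciding which clusters represent the same marker.  Gaps are stripped
#' before k-mers are extracted; the similarity is the Jaccard index of
#' the two k-mer sets, symmetric and in `[0, 1]`.
#'
#' @param a,b residue strings or character vectors.
#' @param kmer_size k-mer length (default 8, must be >= 2).
#' @return similarity in `[0, 1]`; 0 with a warning if either sequence is
#'   shorter than `kmer_size` after gap removal.
#' @export
seed_similarity <- function(a, b, kmer_size = 8L) {
  stopifnot(kmer_size >= 2L)
  ka <- kmer_set(a, kmer_size); kb <- kmer_set(b, kmer_size)
  if (!length(ka) || !length(kb)) {
    warning("sequence shorter than kmer_size; similarity set to 0")
    return(0)
  }
  length(intersect(ka, kb)) / length(union(ka, kb))
}

kmer_set <- function(x, k) {
  chars <- seq_chars(x)
  chars <- chars[chars != "-"]
  n <- length(chars)
  if (n < k) return(character())
  unique(vapply(seq_len(n - k + 1L),
                function(i) paste(chars[i:(i + k - 1L)], collapse = ""), ""))
}

#' Group clusters whose seeds are similar (single linkage)
#'
#' Two clusters end up in the same group when they are connected by a
#' chain of seed pairs with similarity at or above the threshold, i.e.
#' connected components of the thresholded seed-similarity graph.  Group
#' ids are deterministic: the lexicographically smallest member
#' cluster_id.
#'
#' @param clusters list of [seq_cluster()] objects.
#' @param kmer_size,min_similarity see [seed_similarity()];
#'   `min_similarity` defaults to 0.5.
#' @return named list of character vectors of cluster ids (a partition
#'   of the input), names being the group ids.
#' @export
merge_sister_clusters <- function(clusters, kmer_size = 8L,
                                  min_similarity = 0.5) {
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  if (anyDuplicated(ids)) stop("duplicate cluster ids")
  n <- length(clusters)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  seeds <- lapply(clusters, `[[`, "seed_seq")
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- seed_similarity(seeds[[i]], seeds[[j]], kmer_size)
    if (s >= min_similarity) parent[max(find(i), find(j))] <- min(find(i), find(j))
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  names(groups) <- vapply(groups, `[`, "", 1L)
  groups[order(names(groups))]
}

# ---- profile alignment ------------------------------------------------------

profile_freqs <- function(mat, alphabet) {
  f <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = alphabet))
    as.numeric(tab) / length(col)
  })
  matrix(f, nrow = length(alphabet), dimnames = list(alphabet, NULL))
}

#' Merge two alignments by profile alignment
#'
#' Global dynamic programming over column-frequency profiles with
#' sum-of-pairs expected scoring (`match`/`mismatch` between residues,
#' `gap` for residue-vs-gap, 0 for gap-vs-gap) and free terminal gaps.
#' Columns of each input keep their relative order and no residue is ever
#' reordered or deleted within a row; where one profile takes a gap, an
#' all-gap column is inserted for its rows.
#'
#' @param a,b aligned character matrices (rows = sequences).
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return merged character matrix: rows of `a` followed by rows of `b`.
#' @export
profile_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (is.null(dim(a)) || is.null(dim(b))) stop("inputs must be aligned matrices")
  alphabet <- sort(unique(c(as.vector(a), as.vector(b), "-")))
  fa <- profile_freqs(a, alphabet); fb <- profile_freqs(b, alphabet)
  ga <- fa["-", , drop = TRUE]; gb <- fb["-", , drop = TRUE]
  pa <- fa[alphabet != "-", , drop = FALSE]
  pb <- fb[alphabet != "-", , drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  cross <- crossprod(pa, pb)                       # sum_x pa[x,i] pb[x,j]
  resa <- 1 - ga; resb <- 1 - gb
  S <- match * cross +
    mismatch * (outer(resa, resb) - cross) +
    gap * (outer(ga, resb) + outer(resa, gb))
  gapA <- gap * resa                                # A column vs all-gap
  gapB <- gap * resb
  H <- matrix(0, na + 1L, nb + 1L)
  P <- matrix(0L, na + 1L, nb + 1L)                 # 1 diag, 2 up, 3 left
  H[, 1] <- 0; H[1, ] <- 0                          # free leading gaps
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cand <- c(H[i, j] + S[i, j], H[i, j + 1L] + gapA[i], H[i + 1L, j] + gapB[j])
    k <- which.max(cand)
    H[i + 1L, j + 1L] <- cand[k]; P[i + 1L, j + 1L] <- k
  }
  # free trailing gaps: best end on the last row or column; on ties prefer
  # the end consuming most columns (so alignment beats skipping everything)
  ends <- rbind(cbind(na + 1L, seq_len(nb + 1L)), cbind(seq_len(na), nb + 1L))
  k <- order(-H[ends], -(ends[, 1] + ends[, 2]))[1]
  best <- ends[k, ]
  i <- best[1]; j <- best[2]
  steps <- list()
  emit <- function(ai, bj) steps[[length(steps) + 1L]] <<- c(ai, bj)
  for (k in seq_len(na - (i - 1L))) emit(na - k + 1L, 0L)   # trailing A cols
  for (k in seq_len(nb - (j - 1L))) emit(0L, nb - k + 1L)   # trailing B cols
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L && P[i, j] == 1L) { emit(i - 1L, j - 1L); i <- i - 1L; j <- j - 1L }
    else if (i > 1L && (j == 1L || P[i, j] == 2L)) { emit(i - 1L, 0L); i <- i - 1L }
    else { emit(0L, j - 1L); j <- j - 1L }
  }
  steps <- rev(steps)
  out <- matrix("-", nrow(a) + nrow(b), length(steps))
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    if (st[1] > 0L) out[seq_len(nrow(a)), k] <- a[, st[1]]
    if (st[2] > 0L) out[nrow(a) + seq_len(nrow(b)), k] <- b[, st[2]]
  }
  rownames(out) <- c(rownames(a), rownames(b))
  out
}

#' Merge a group of aligned clusters into one alignment
#'
#' Clusters are profile-aligned pairwise in lexicographic cluster-id
#' order (the deterministic group order from
#' [merge_sister_clusters()]).
#'
#' @param clusters list of aligned [seq_cluster()] objects.
#' @param merged_id id for the merged cluster.
#' @param ... scoring parameters passed to [profile_align()].
#' @return a merged aligned `seq_cluster`.
#' @export
merge_cluster_group <- function(clusters, merged_id = NULL, ...) {
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  clusters <- clusters[order(ids)]
  mats <- lapply(clusters, function(cl) {
    m <- do.call(rbind, lapply(unname(cl$seqs), seq_chars))
    rownames(m) <- cl$seq_id
    m
  })
  merged <- Reduce(function(x, y) profile_align(x, y, ...), mats)
  species <- unlist(lapply(clusters, `[[`, "species_id"), use.names = FALSE)
  seq_cluster(merged_id %||% sort(ids)[1],
              unlist(lapply(clusters, `[[`, "seq_id"), use.names = FALSE),
              species,
              apply(merged, 1, paste, collapse = ""),
              seed_id = clusters[[1]]$seed_id, aligned = TRUE,
              seed_seq = clusters[[1]]$seed_seq)
}
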