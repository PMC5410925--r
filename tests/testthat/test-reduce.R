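test_that("per-species reduction ranks by ambiguity, then median length", {
  # single sequence per species: unchanged
  cl <- mk_cluster(list(a = "ACGT", b = "ACGA"), species = c("s1", "s2"))
  expect_equal(reduce_cluster(cl)$seq_id, cl$seq_id)

  # lengths 300/480/520, ambiguity 0/0/3, median 480: the 480 one wins
  set.seed(1)
  mk <- function(n, namb) {
    s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    if (namb) s[seq_len(namb)] <- "N"
    paste(s, collapse = "")
  }
  cl2 <- mk_cluster(list(q1 = mk(300, 0), q2 = mk(480, 0), q3 = mk(520, 3)),
                    species = rep("sp", 3))
  expect_equal(reduce_cluster(cl2, keep = 1)$seq_id, "q2")

  # equal lengths, ambiguity counts 5 vs 0: fewest ambiguities wins
  cl3 <- mk_cluster(list(q1 = paste0(strrep("N", 5), strrep("A", 95)),
                         q2 = strrep("A", 100)),
                    species = rep("sp", 2))
  expect_equal(reduce_cluster(cl3, keep = 1)$seq_id, "q2")
})

test_that("reduction is idempotent and remembers a dropped seed", {
  set.seed(42)
  seqs <- lapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE,
                 prob = c(.24, .24, .24, .24, .04)), collapse = ""))
  names(seqs) <- paste0("q", 1:6)
  cl <- mk_cluster(seqs, species = rep(c("s1", "s2"), each = 3), seed = "q3")
  r1 <- reduce_cluster(cl, keep = 1)
  r2 <- reduce_cluster(r1, keep = 1)
  expect_equal(r1$seq_id, r2$seq_id)
  expect_equal(r1$seqs, r2$seqs)
  expect_equal(r1$seed_id, "q3")               # remembered even if dropped
  expect_equal(r1$seed_seq, unname(cl$seqs["q3"]))
})

test_that("seed similarity is the k-mer Jaccard index", {
  expect_equal(seed_similarity("ACGTACGTAC", "ACGTACGTAC", 4), 1.0)
  expect_equal(seed_similarity("AAAAAAAA", "CCCCCCCC", 4), 0.0)
  # brute-force oracle on the worked pair
  a <- "ACGTACGTAC"; b <- "ACGTACGTAA"; k <- 4
  kms <- function(x) unique(sapply(1:(nchar(x) - k + 1),
                                   function(i) substr(x, i, i + k - 1)))
  expected <- length(intersect(kms(a), kms(b))) / length(union(kms(a), kms(b)))
  expect_equal(seed_similarity(a, b, k), expected)
  expect_equal(seed_similarity(a, b, k), seed_similarity(b, a, k))
  expect_warning(s <- seed_similarity("ACG", "ACGTACGT", 8), "shorter")
  expect_equal(s, 0)
})

test_that("sister-cluster merging is single linkage on seed similarity", {
  mk <- function(id, seedseq)
    mk_cluster(stats::setNames(list(seedseq), paste0(id, "_seed")), id = id)
  # A~B and B~C similar, A~C not: one group by transitivity
  a <- strrep("ACGTACGTGGCCTTAA", 4)
  b <- paste0(substr(a, 1, 40), strrep("TTGACGAC", 3))
  c <- paste0(substr(b, 33, 64), strrep("GGTTCCAA", 4))
  cl <- list(mk("cA", a), mk("cB", b), mk("cC", c))
  sims <- c(AB = seed_similarity(a, b), BC = seed_similarity(b, c),
            AC = seed_similarity(a, c))
  thr <- min(sims[c("AB", "BC")]) - 0.01
  expect_true(sims["AC"] < thr)       # fixture really is a chain
  g <- merge_sister_clusters(cl, min_similarity = thr)
  expect_equal(length(g), 1L)
  expect_equal(sort(g[[1]]), c("cA", "cB", "cC"))

  # all dissimilar: every cluster its own group
  g2 <- merge_sister_clusters(cl, min_similarity = 0.99)
  expect_equal(lengths(g2), c(cA = 1L, cB = 1L, cC = 1L))
})

test_that("merging equals brute-force connected components (property)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:8, 1)
    seqs <- sapply(1:n, function(i)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""))
    cl <- lapply(1:n, function(i)
      mk_cluster(stats::setNames(list(seqs[i]), paste0("s", i)),
                 id = sprintf("c%02d", i)))
    thr <- runif(1, 0.05, 0.6)
    got <- merge_sister_clusters(cl, min_similarity = thr)
    # oracle: igraph components on the thresholded similarity graph
    adj <- outer(1:n, 1:n, Vectorize(function(i, j)
      i != j && seed_similarity(seqs[i], seqs[j]) >= thr))
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
    want <- lapply(split(sprintf("c%02d", 1:n), comp), sort)
    names(want) <- vapply(want, `[`, "", 1L)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("profile alignment merges profiles without touching row content", {
  a <- matrix(c("A", "C", "A", "C"), 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), NULL))
  b <- matrix(c("A", "G", "C"), 1, dimnames = list("r3", NULL))
  m <- profile_align(a, b)
  expect_equal(ncol(m), 3L)                       # one gap column inserted
  expect_equal(nrow(m), 3L)
  strip <- function(x) x[x != "-"]
  expect_equal(strip(m["r1", ]), c("A", "C"))
  expect_equal(strip(m["r3", ]), c("A", "G", "C"))

  # exhaustive oracle over the 2x3 lattice: achieved score is optimal.
  # Scoring universe: all cross-profile row pairs; terminal gaps free.
  score_cols <- function(ca, cb) {
    s <- 0
    for (x in ca) for (y in cb)
      s <- s + (if (x == "-" && y == "-") 0
                else if (x == "-" || y == "-") -2
                else if (x == y) 1 else -1)
    s
  }
  gapsA <- rep("-", nrow(a)); gapsB <- rep("-", nrow(b))
  best <- -Inf
  walk <- function(i, j, sc) {
    if (i == 2 && j == 3) { best <<- max(best, sc); return() }
    if (i < 2 && j < 3)
      walk(i + 1, j + 1, sc + score_cols(a[, i + 1], b[, j + 1]))
    if (i < 2) walk(i + 1, j,
                    sc + (if (j == 0 || j == 3) 0
                          else score_cols(a[, i + 1], gapsB)))
    if (j < 3) walk(i, j + 1,
                    sc + (if (i == 0 || i == 2) 0
                          else score_cols(gapsA, b[, j + 1])))
  }
  walk(0, 0, 0)
  # cross-profile score achieved by the returned merge; all-gap columns of
  # a profile are free only in its terminal (leading/trailing) stretch
  occupied <- function(rows) {
    has <- apply(m[rows, , drop = FALSE], 2, function(x) any(x != "-"))
    range(which(has))
  }
  ra <- occupied(1:2); rb <- occupied(3)
  got <- sum(sapply(seq_len(ncol(m)), function(k) {
    ca <- m[1:2, k]; cb <- m[3, k]
    a_term <- all(ca == "-") && (k < ra[1] || k > ra[2])
    b_term <- all(cb == "-") && (k < rb[1] || k > rb[2])
    if (a_term || b_term) 0 else score_cols(ca, cb)
  }))
  expect_equal(got, best)

  # merging an alignment with itself adds no gap columns
  self <- profile_align(a, a)
  expect_equal(ncol(self), ncol(a))
  expect_false(any(self == "-"))
})

test_that("profile alignment preserves ungapped row content (property)", {
  for (seed in 1:8) {
    set.seed(seed)
    a <- matrix(sample(c("A", "C", "G", "T", "-"), 3 * 8, TRUE), 3,
                dimnames = list(paste0("a", 1:3), NULL))
    b <- matrix(sample(c("A", "C", "G", "T", "-"), 2 * 11, TRUE), 2,
                dimnames = list(paste0("b", 1:2), NULL))
    m <- profile_align(a, b)
    for (r in rownames(a))
      expect_equal(m[r, ][m[r, ] != "-"], a[r, ][a[r, ] != "-"])
    for (r in rownames(b))
      expect_equal(m[r, ][m[r, ] != "-"], b[r, ][b[r, ] != "-"])
  }
})
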