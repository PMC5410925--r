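test_that("average divergence excludes saturated pairs but counts them", {
  m <- rbind(a = rep("A", 10), b = rep("A", 10))
  expect_equal(as.numeric(average_divergence(m)), 0)

  # three rows with pairwise p-distances 0.1 / 0.2 / 0.1
  r1 <- strsplit(strrep("A", 10), "")[[1]]
  r2 <- r1; r2[1] <- "C"             # p(r1,r2) = 0.1
  r3 <- r1; r3[1] <- "C"; r3[2] <- "G"   # p(r1,r3) = 0.2, p(r2,r3) = 0.1
  m2 <- rbind(x = r1, y = r2, z = r3)
  expect_equal(as.numeric(average_divergence(m2, model = "p")),
               mean(c(0.1, 0.2, 0.1)), tolerance = 1e-12)

  # one saturated pair among three: mean of the remaining two
  x <- r1
  w <- c(rep("C", 8), "A", "A")       # p(x,w) = 0.8: saturated
  y <- c(rep("C", 5), rep("A", 5))    # p(x,y) = 0.5, p(y,w) = 0.3
  m3 <- rbind(x = x, y = y, w = w)
  av <- average_divergence(m3)
  expect_equal(attr(av, "saturated"), 1L)
  expect_equal(as.numeric(av),
               mean(c(pairwise_distance(x, y), pairwise_distance(y, w))))

  all_sat <- rbind(x = r1, y = rep("C", 10))
  expect_error(average_divergence(all_sat), "saturated")
})

test_that("the greedy assembler reproduces the hand-traced example", {
  occ <- matrix(0L, 4, 4, dimnames = list(paste0("S", 1:4), paste0("A", 1:4)))
  occ["S1", c("A1", "A4")] <- 1L
  occ["S2", c("A1", "A2")] <- 1L
  occ["S3", c("A1", "A2", "A3")] <- 1L
  occ["S4", c("A1", "A2", "A3")] <- 1L
  res <- assemble_supermatrix(occupancy_to_alignments(occ), rownames(occ),
                              min_markers = 1, max_markers = 2)
  expect_equal(res$selected, c("A1", "A4", "A2"))
  expect_setequal(res$retained, rownames(occ))
  expect_equal(nrow(res$dropped), 0L)

  # everyone everywhere, min = max = 1: single highest-coverage alignment
  occ2 <- matrix(1L, 3, 3, dimnames = list(paste0("S", 1:3), paste0("A", 1:3)))
  res2 <- assemble_supermatrix(occupancy_to_alignments(occ2), rownames(occ2),
                               min_markers = 1, max_markers = 1)
  expect_equal(res2$selected, "A1")   # coverage ties break lexicographically

  # a species in one candidate with min = 2 is dropped and reported
  occ3 <- matrix(0L, 3, 3, dimnames = list(paste0("S", 1:3), paste0("A", 1:3)))
  occ3["S1", c("A1", "A2")] <- 1L
  occ3["S2", c("A1", "A2", "A3")] <- 1L
  occ3["S3", "A3"] <- 1L
  res3 <- assemble_supermatrix(occupancy_to_alignments(occ3), rownames(occ3),
                               min_markers = 2, max_markers = 3)
  expect_true("S3" %in% res3$dropped$species_id)
  expect_false("S3" %in% res3$retained)
})

test_that("assembler matches the step-by-step reference simulator", {
  for (seed in 1:40) {
    occ <- rand_occupancy(seed)
    minm <- sample(1:2, 1); maxm <- minm + sample(0:2, 1)
    want <- reference_knapsack(occ, minm, maxm)
    got <- assemble_supermatrix(occupancy_to_alignments(occ), rownames(occ),
                                min_markers = minm, max_markers = maxm)
    expect_equal(got$selected, want$selected, info = paste("seed", seed))
    expect_equal(got$retained, want$retained)
    expect_equal(sort(got$dropped$species_id), want$dropped)
    # every retained species meets min coverage
    counts <- rowSums(occ[got$retained, got$selected, drop = FALSE])
    expect_true(all(counts >= minm))
    # determinism under permuted input order
    alns <- occupancy_to_alignments(occ)
    got2 <- assemble_supermatrix(alns[sample(length(alns))], rownames(occ),
                                 min_markers = minm, max_markers = maxm)
    expect_equal(got2$selected, got$selected)
  }
})

test_that("saturated alignments are excluded before assembly", {
  good <- rbind(S1 = rep("A", 40),
                S2 = c("C", rep("A", 39)))          # p = 0.025
  sat <- rbind(S1 = rep("A", 40), S2 = rep("C", 40))
  res <- assemble_supermatrix(list(a_good = good, b_sat = sat),
                              c("S1", "S2"), 1, 2,
                              max_avg_divergence = 0.25)
  expect_equal(res$excluded_alignments, "b_sat")
  expect_false("b_sat" %in% res$selected)
  expect_error(assemble_supermatrix(list(b_sat = sat), c("S1", "S2"), 1, 1),
               "divergence filter")
})

test_that("concatenation tiles partitions and fills missing with ?", {
  a1 <- rand_alignment(c("S1", "S2", "S3"), 5, 1)
  a2 <- rand_alignment(c("S1", "S3"), 7, 2)
  conc <- concatenate_alignments(list(a1 = a1, a2 = a2), c("a1", "a2"),
                                 c("S1", "S2", "S3"))
  expect_equal(ncol(conc$matrix), 12L)
  expect_equal(conc$partitions$start, c(1L, 6L))
  expect_equal(conc$partitions$end, c(5L, 12L))
  expect_equal(sum(conc$matrix["S2", ] == "?"), 7L)
  expect_error(concatenate_alignments(list(a1 = a1), character(), "S1"),
               "empty")
  dup <- rbind(a1, a1[1, , drop = FALSE])
  expect_error(concatenate_alignments(list(d = dup), "d", rownames(dup)),
               "duplicate")
})

test_that("marker-graph statistics match hand-computed values", {
  # everyone shares one alignment: complete graph
  occ <- matrix(TRUE, 4, 1, dimnames = list(paste0("S", 1:4), "A1"))
  st <- marker_graph_stats(occ)
  expect_equal(st$density, 1)
  expect_equal(st$mean_path_length, 1)
  expect_equal(st$components, 1L)

  # two disjoint blocks: 2 components
  occ2 <- cbind(A1 = c(TRUE, TRUE, FALSE, FALSE),
                A2 = c(FALSE, FALSE, TRUE, TRUE))
  rownames(occ2) <- paste0("S", 1:4)
  expect_equal(marker_graph_stats(occ2)$components, 2L)

  # path graph S1-S2-S3: density 2/3, mean path (1+1+2)/3
  occ3 <- cbind(A1 = c(TRUE, TRUE, FALSE), A2 = c(FALSE, TRUE, TRUE))
  rownames(occ3) <- paste0("S", 1:3)
  st3 <- marker_graph_stats(occ3)
  expect_equal(st3$density, 2 / 3)
  expect_equal(st3$mean_path_length, 4 / 3)
})
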