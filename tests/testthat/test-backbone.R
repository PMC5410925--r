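test_that("NJ recovers additive distance structure", {
  # additive 4x4: d(A,B) = 2, d(C,D) = 2, all cross pairs = 4
  d <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  phy <- ape::nj(stats::as.dist(d))
  split <- names(phylograft:::split_table(phy))
  expect_equal(split, "C;D")                       # split AB|CD, canonical side
  internal <- phy$edge.length[phy$edge[, 2] > ape::Ntip(phy)]
  expect_equal(internal[internal > 0], 2)          # internal branch length 2
})

test_that("NJ on sequence matrices clamps negatives and is deterministic", {
  set.seed(9)
  truth <- rand_ultrametric(6, 9)
  spec <- list(Q = rep(1, 6), bf = rep(0.25, 4), shape = NA,
               length = 2000, rate = 0.01)
  mat <- simulate_alignment(truth, spec, truth$tip.label, seed = 9)
  phy <- nj_tree(mat)
  expect_true(all(phy$edge.length >= 0))
  expect_equal(ape::write.tree(phy), ape::write.tree(nj_tree(mat)))
  # long, clean alignment recovers the generating topology
  expect_equal(rf_distance(phy, truth)$raw, 0)
  # identical rows give a zero-length cherry
  mat2 <- rbind(mat, zz = mat[1, ])
  rownames(mat2)[nrow(mat2)] <- "zz"
  phy2 <- nj_tree(mat2)
  mrca <- ape::getMRCA(phy2, c(rownames(mat)[1], "zz"))
  depth <- ape::node.depth.edgelength(phy2)
  expect_lt(abs(ape::cophenetic.phylo(phy2)[rownames(mat)[1], "zz"]), 1e-9)
})

test_that("NJ recovers the topology of random additive matrices (n <= 6)", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(4:6, 1)
    truth <- ape::rtree(n, tip.label = sprintf("t%d", 1:n))
    truth$edge.length <- runif(nrow(truth$edge), 0.5, 2)
    d <- ape::cophenetic.phylo(truth)
    got <- ape::nj(stats::as.dist(d))
    expect_equal(rf_distance(got, truth)$raw, 0, info = paste("seed", seed))
  }
})

test_that("bootstrap support is seeded and tracks signal strength", {
  set.seed(4)
  truth <- rand_ultrametric(8, 4)
  spec <- list(Q = rep(1, 6), bf = rep(0.25, 4), shape = NA,
               length = 3000, rate = 0.02)
  mat <- simulate_alignment(truth, spec, truth$tip.label, seed = 4)
  bs <- bootstrap_support(mat, replicates = 50, seed = 11)
  bs2 <- bootstrap_support(mat, replicates = 50, seed = 11)
  expect_identical(bs$support, bs2$support)
  expect_gte(min(bs$support), 0)
  expect_lte(max(bs$support), 1)
  expect_gte(mean(bs$support), 0.9)      # strong signal: high mean support
  # random data: mean internal support drops below the clean-data support
  noise <- matrix(sample(c("A", "C", "G", "T"), 8 * 300, TRUE), 8,
                  dimnames = list(rownames(mat), NULL))
  bsn <- suppressWarnings(bootstrap_support(noise, replicates = 50, seed = 11))
  expect_lt(mean(bsn$support), mean(bs$support))
})

test_that("majority consensus keeps clades strictly above the threshold", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  # identical trees: consensus is the tree, all supports 1
  cons <- majority_consensus(list(t1, t1, t1), 0.5)
  expect_equal(rf_distance(cons, t1)$raw, 0)
  expect_true(all(as.numeric(cons$node.label) == 1))

  # a split in 2 of 3 trees survives with support 2/3
  t2 <- ape::read.tree(text = "((A,B),(C,D));")
  t3 <- ape::read.tree(text = "((A,C),(B,D));")
  cons2 <- majority_consensus(list(t1, t2, t3), 0.5)
  keys <- phylograft:::clade_keys(cons2)
  expect_true("A;B" %in% keys)
  sup <- as.numeric(cons2$node.label)
  expect_true(any(abs(sup - 2 / 3) < 1e-6))

  # two incompatible splits at exactly 0.5 are both excluded (strict >)
  cons3 <- majority_consensus(list(t1, t3), 0.5)
  expect_false("A;B" %in% phylograft:::clade_keys(cons3))
  expect_false("A;C" %in% phylograft:::clade_keys(cons3))
  expect_error(majority_consensus(list(t1, ape::read.tree(text = "((A,B),(C,E));"))),
               "tip sets")
})

test_that("fossil placement maps, combines and detects conflicts", {
  phy <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  cal <- data.frame(calib_id = c("root", "ab1", "ab2"),
                    min_age = c(30, 10, 12), max_age = c(40, NA, NA))
  cal$taxa <- list(c("A", "D"), c("A", "B"), c("A", "B"))
  pl <- place_fossils(phy, cal)
  root_node <- ape::Ntip(phy) + 1L
  ab_node <- ape::getMRCA(phy, c("A", "B"))
  expect_setequal(pl$node, c(root_node, ab_node))
  expect_equal(pl$min_age[pl$node == ab_node], 12)   # max of the minima
  expect_equal(pl$max_age[pl$node == root_node], 40)

  # descendant minimum above ancestor maximum: conflict
  bad <- data.frame(calib_id = c("anc", "desc"), min_age = c(5, 20),
                    max_age = c(15, NA))
  bad$taxa <- list(c("A", "D"), c("A", "B"))
  expect_error(place_fossils(phy, bad), "conflict")

  # absent taxon: skipped with a warning
  mis <- data.frame(calib_id = "gone", min_age = 5, max_age = NA)
  mis$taxa <- list(c("A", "Z"))
  expect_warning(expect_error(place_fossils(phy, mis), "no calibration"),
                 "skipped")
  # partial mode uses the taxa that are present
  mis2 <- data.frame(calib_id = "part", min_age = 1, max_age = NA)
  mis2$taxa <- list(c("A", "B", "Z"))
  expect_equal(suppressWarnings(place_fossils(phy, mis2, partial = TRUE))$node,
               ab_node)
})

test_that("MPL-scale dating satisfies minima and respects maxima", {
  # clock-like phylogram: relative root age 1, calibration min 10
  phy <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  cal <- data.frame(calib_id = "r", min_age = 10, max_age = NA)
  cal$taxa <- list(c("A", "C"))
  dated <- date_tree(phy, calibrations = cal)
  ages <- node_ages(dated)
  expect_equal(max(ages), 10)
  expect_equal(sort(unique(round(ages, 9))), c(0, 5, 10))
  validate_chronogram(dated)

  # an already-calibrated ultrametric tree is unchanged
  dated2 <- date_tree(dated$phy, calibrations = cal)
  expect_equal(node_ages(dated2), node_ages(dated), tolerance = 1e-12)

  # two placements where one minimum forces another's maximum violated:
  # the root minimum needs f >= 10, pushing the AB node (relative age
  # 0.5) to 5, above its maximum of 4
  cal2 <- data.frame(calib_id = c("r", "ab"), min_age = c(10, 1),
                     max_age = c(NA, 4))
  cal2$taxa <- list(c("A", "C"), c("A", "B"))
  expect_error(date_tree(phy, calibrations = cal2), "unsatisfiable")
})

test_that("node-age HPDs come from the dated tree sample", {
  set.seed(2)
  truth <- rand_ultrametric(6, 2)
  spec <- list(Q = rep(1, 6), bf = rep(0.25, 4), shape = NA,
               length = 800, rate = 0.02)
  mat <- simulate_alignment(truth, spec, truth$tip.label, seed = 2)
  bs <- bootstrap_support(mat, replicates = 20, seed = 3)
  cal <- data.frame(calib_id = "r", min_age = 10, max_age = NA)
  cal$taxa <- list(truth$tip.label[1:2])
  dated <- date_tree(bs$tree, calibrations = cal, partial = TRUE)
  withhpd <- date_with_sample(dated, bs$replicates, cal, partial = TRUE)
  expect_gt(sum(!is.na(withhpd$data$hpd_min)), 0)
  validate_chronogram(withhpd)
})
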