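test_that("the birth-death likelihood matches ape's fit", {
  tr <- simulate_bd_tree(0.3, 0.1, 30, seed = 5)
  fit <- fit_birth_death(tr)
  ref <- ape::birthdeath(tr$phy)     # independent implementation
  expect_equal(fit$loglik, -ref$dev / 2, tolerance = 1e-4)
  expect_equal(unname(fit$epsilon), unname(ref$para["d/b"]), tolerance = 1e-3)
  expect_equal(unname(fit$r), unname(ref$para["b-d"]), tolerance = 1e-3)
  expect_gte(fit$mu, 0)
})

test_that("the optimum beats a grid search over (r, epsilon)", {
  tr <- simulate_bd_tree(0.4, 0.2, 60, seed = 8)
  fit <- fit_birth_death(tr)
  bt <- unname(ape::branching.times(tr$phy))
  rs <- seq(0.01, 1, length.out = 50)
  eps <- seq(0, 0.98, length.out = 50)
  grid_max <- max(outer(rs, eps, Vectorize(function(r, a)
    phylograft:::bd_loglik(r, a, bt))))
  expect_gte(fit$loglik, grid_max - 1e-6)
})

test_that("tree simulation is conditioned, ultrametric and seeded", {
  tr <- simulate_bd_tree(0.5, 0.2, 25, seed = 3)
  expect_equal(ape::Ntip(tr$phy), 25L)
  validate_chronogram(tr)
  expect_identical(write_tree(simulate_bd_tree(0.5, 0.2, 25, seed = 3)),
                   write_tree(tr))
  expect_false(identical(write_tree(simulate_bd_tree(0.5, 0.2, 25, seed = 4)),
                         write_tree(tr)))
  # two-tip pure-birth: root age ~ Exp(2 lambda), mean 1/(2 lambda)
  roots <- vapply(1:2000, function(s)
    max(node_ages(simulate_bd_tree(0.5, 0, 2, seed = s))), 0)
  expect_equal(mean(roots), 1 / (2 * 0.5), tolerance = 0.1)
})

test_that("genus assignment mirrors a reference size profile", {
  # perfectly balanced 8-tip tree, reference sizes {4, 4}
  phy <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  prof <- data.frame(genus = c("g1", "g2"), size = c(4, 4),
                     crown_age = c(2, 2))
  asg <- assign_genera(chronogram(phy), prof, seed = 1)
  expect_setequal(unique(asg$genus_map[c("a", "b", "c", "d")]),
                  asg$genus_map[["a"]])
  expect_setequal(unique(asg$genus_map[c("e", "f", "g", "h")]),
                  asg$genus_map[["e"]])
  expect_equal(sort(unique(unname(asg$genus_map))), c("g1", "g2"))

  # all-monotypic reference: every tip its own genus
  prof2 <- data.frame(genus = paste0("m", 1:8), size = 1, crown_age = 0)
  asg2 <- assign_genera(chronogram(phy), prof2, seed = 1)
  expect_equal(length(unique(asg2$genus_map)), 8L)

  # genera are monophyletic by construction on random trees, and the
  # size distribution stays close to the target
  for (seed in 1:5) {
    tr <- simulate_bd_tree(0.4, 0.1, 20, seed = 100 + seed)
    prof3 <- data.frame(genus = c("x", "y", "z"), size = c(6, 4, 2),
                        crown_age = c(3, 2, 1))
    asg3 <- assign_genera(tr, prof3, seed = seed)
    taxa <- data.frame(species_id = names(asg3$genus_map),
                       species_name = names(asg3$genus_map),
                       genus = unname(asg3$genus_map))
    expect_true(all(assess_monophyly(tr$phy, taxa)$monophyletic))
    tv <- sum(abs(asg3$report$achieved_size - asg3$report$target_size))
    expect_lte(tv / sum(prof3$size), 0.5)
  }
})

test_that("substitution-model selection respects nesting and recovers JC", {
  tr <- rand_ultrametric(8, 21)
  spec <- list(Q = rep(1, 6), bf = rep(0.25, 4), shape = NA,
               length = 1200, rate = 0.02)
  hits <- 0L
  for (s in 1:5) {
    mat <- simulate_alignment(tr, spec, tr$tip.label, seed = 300 + s)
    fit <- fit_subst_model(mat)
    if (fit$model %in% c("JC", "K80")) hits <- hits + 1L
    # nested models cannot lose likelihood
    tab <- fit$aic_table
    ll <- function(m, g) {
      i <- which(tab$model == m & tab$gamma == g)
      # recover loglik from AIC is enough for ordering within one data set
      -tab$aic[i] / 2
    }
    expect_gte(ll("GTR", FALSE) + 1e-4, ll("JC", FALSE) - 8)  # df penalty bound
  }
  expect_gte(hits, 4L)               # simple-model family selected
})

test_that("HKY kappa is recovered from simulated data", {
  tr <- rand_ultrametric(8, 22)
  spec <- list(Q = c(1, 4, 1, 1, 4, 1), bf = c(0.3, 0.2, 0.2, 0.3),
               shape = NA, length = 4000, rate = 0.02)
  mat <- simulate_alignment(tr, spec, tr$tip.label, seed = 77)
  fit <- fit_subst_model(mat, models = c("HKY"), try_gamma = FALSE)
  kappa_hat <- fit$Q[2] / fit$Q[1]
  expect_gt(kappa_hat, 2.5)
  expect_lt(kappa_hat, 6)
})

test_that("sequence simulation matches the JC expected divergence", {
  # two tips, path length t: E[p] = 3/4 (1 - exp(-4 rt/3))
  phy <- ape::read.tree(text = "(A:5,B:5);")
  rate <- 0.02; t_path <- 10
  spec <- list(Q = rep(1, 6), bf = rep(0.25, 4), shape = NA,
               length = 20000, rate = rate)
  mat <- simulate_alignment(chronogram(phy), spec, c("A", "B"), seed = 12)
  p_hat <- mean(mat["A", ] != mat["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * rate * t_path / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 20000)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # zero-length branches: all rows identical
  phy0 <- ape::read.tree(text = "(A:0,B:0);")
  m0 <- simulate_alignment(chronogram(phy0), spec, c("A", "B"), seed = 1)
  expect_identical(m0["A", ], m0["B", ])

  # same seed, same alignment
  expect_identical(simulate_alignment(chronogram(phy), spec, c("A", "B"),
                                      seed = 12), mat)
})

test_that("replication mirrors occupancy and drops invariable clusters", {
  bundle <- simulate_reference_bundle(n_species = 15, n_genera = 4,
                                      n_clusters = 3, seq_length = 400,
                                      seed = 11)
  # a nearly invariable reference cluster should replicate to an
  # invariable alignment and be dropped
  flat <- matrix("A", 6, 50,
                 dimnames = list(rownames(bundle$clusters[[1]])[1:6], NULL))
  flat[1, 1] <- "C"
  bundle$clusters$flat <- flat
  rep <- replicate_dataset(bundle[c("tree", "clusters", "taxa")],
                           seed = 4, models = c("JC", "HKY"))
  expect_true("flat" %in% rep$dropped_invariable)
  # occupancy of surviving clusters is identical under the mapping
  for (id in names(rep$clusters)) {
    want <- sort(unname(rep$mapping[intersect(
      rownames(bundle$clusters[[id]]), names(rep$mapping))]))
    expect_equal(sort(rownames(rep$clusters[[id]])), want, info = id)
  }
  expect_equal(ape::Ntip(rep$tree$phy), 15L)
  # genus structure mirrored: same number of multi-species genera
  expect_s3_class(rep$summary, "data.frame")
  # paired-seed recovery: fitting the replicate tree returns rates in a
  # plausible band around the reference fit
  bd_ref <- fit_birth_death(bundle$tree)
  bd_rep <- fit_birth_death(rep$tree)
  expect_lt(abs(bd_rep$lambda - bd_ref$lambda) / bd_ref$lambda, 1.5)
})

test_that("site-pattern frequencies follow the stationary distribution", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  bf <- c(0.4, 0.3, 0.2, 0.1)
  spec <- list(Q = rep(1, 6), bf = bf, shape = NA, length = 30000,
               rate = 0.001)
  mat <- simulate_alignment(chronogram(phy), spec, c("A", "B"), seed = 6)
  freq <- table(factor(mat["A", ], levels = c("A", "C", "G", "T"))) / 30000
  expect_lt(max(abs(as.numeric(freq) - bf)), 0.012)   # ~4 multinomial sds
})
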