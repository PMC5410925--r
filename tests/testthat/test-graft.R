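mk_taxa <- function(map) {
  data.frame(species_id = names(map), species_name = names(map),
             genus = unname(map), stringsAsFactors = FALSE)
}

test_that("monophyly is judged from the exemplars' MRCA clade", {
  taxa <- mk_taxa(c(A1 = "A", A2 = "A", C1 = "C", C2 = "C",
                    D1 = "D", D2 = "D"))
  phy <- ape::read.tree(text = "((A1,A2),((C1,D1),(C2,D2)));")
  v <- assess_monophyly(phy, taxa)
  expect_true(v$monophyletic[v$genus == "A"])
  expect_false(v$monophyletic[v$genus == "C"])
  expect_false(v$monophyletic[v$genus == "D"])

  # reciprocally monophyletic cherries
  phy2 <- ape::read.tree(text = "((A1,A2),((C1,C2),(D1,D2)));")
  expect_true(all(assess_monophyly(phy2, taxa)$monophyletic))

  # a polytomy mixing two genera flags both
  phy3 <- ape::read.tree(text = "((A1,A2),(C1,D1,C2,D2));")
  v3 <- assess_monophyly(phy3, taxa)
  expect_false(v3$monophyletic[v3$genus == "C"])
  expect_false(v3$monophyletic[v3$genus == "D"])
})

fig2_setup <- function() {
  taxa <- mk_taxa(c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B",
                    B3 = "B", C1 = "C", C2 = "C", C3 = "C",
                    D1 = "D", D2 = "D", D3 = "D"))
  nwk <- "(((A1:1,A2:1):3,(B1:2,B2:2):2):2,((C1:1,D1:1):2,(C2:1,D2:1):2):3);"
  dated <- chronogram(ape::read.tree(text = nwk))
  alns <- lapply(1:3, function(i)
    rand_alignment(taxa$species_id, 60, 400 + i))
  names(alns) <- paste0("a", 1:3)
  list(taxa = taxa, dated = dated, alns = alns)
}

test_that("interdigitated genera merge into one clade task", {
  s <- fig2_setup()
  tasks <- build_clade_tasks(s$dated$phy, s$dated, s$taxa, s$alns)
  ids <- sort(vapply(tasks, `[[`, "", "task_id"))
  expect_equal(ids, c("A", "B", "C+D"))
  cd <- tasks[[which(ids == "C+D")]]
  expect_setequal(cd$genera, c("C", "D"))
  expect_setequal(cd$species, c("C1", "C2", "C3", "D1", "D2", "D3"))
  expect_setequal(cd$exemplars, c("C1", "C2", "D1", "D2"))
  # calibration age = dated MRCA age of all four exemplars
  expect_equal(cd$calibration_age, 3)
  # every task alignment holds >= 2 task species
  expect_true(all(vapply(cd$alignment_ids, function(id)
    sum(rownames(s$alns[[id]]) %in% cd$species) >= 2, TRUE)))

  # all monophyletic: one task per multi-species genus
  phy2 <- ape::read.tree(
    text = "(((A1:1,A2:1):3,(B1:2,B2:2):2):2,((C1:1,C2:1):2,(D1:2,D2:2):1):3);")
  tasks2 <- build_clade_tasks(phy2, chronogram(phy2), s$taxa, s$alns)
  expect_equal(sort(vapply(tasks2, `[[`, "", "task_id")),
               c("A", "B", "C", "D"))
})

test_that("merging chains to a fixed point", {
  taxa <- mk_taxa(c(A1 = "A", A2 = "A", B1 = "B", B2 = "B",
                    C1 = "C", C2 = "C", X1 = "X", X2 = "X"))
  # A and B interleave; B and C interleave; X is clean
  nwk <- "(((((A1:1,B1:1):1,(A2:1,B2:1):1):1,(C1:2,C2:2):1):1,(X1:1,X2:1):3):0);"
  phy <- ape::read.tree(text = "((((A1:1,B1:1):1,(A2:1,C1:1):1):1,(B2:2,C2:2):1):1,(X1:1,X2:1):3);"
  )
  tasks <- build_clade_tasks(phy, chronogram(phy), taxa,
                             list(a = rand_alignment(taxa$species_id, 40, 7)))
  ids <- sort(vapply(tasks, `[[`, "", "task_id"))
  expect_equal(ids, c("A+B+C", "X"))
})

test_that("rescaling multiplies branch lengths and HPDs by one factor", {
  # exemplar MRCA at relative age 2, root at 3, backbone age 10: f = 5
  nwk <- "((E1:2,(E2:1,S1:1)[&hpd_min=0.5,hpd_max=1.5]:1)[&hpd_min=1.5,hpd_max=2.5]:1,S2:3);"
  sub <- read_tree(text = nwk)
  task <- list(task_id = "g", exemplars = c("E1", "E2"),
               calibration_age = 10)
  resc <- rescale_subtree(sub, task)
  expect_equal(attr(resc, "scale_factor"), 5)
  ages <- node_ages(resc)
  expect_equal(max(ages), 15)                                  # root 3 -> 15
  expect_equal(ages[ape::getMRCA(resc$phy, c("E1", "E2"))], 10)
  hpd <- resc$data[!is.na(resc$data$hpd_min), ]
  expect_setequal(round(hpd$hpd_min, 9), c(2.5, 7.5))
  expect_setequal(round(hpd$hpd_max, 9), c(7.5, 12.5))

  # exemplars spanning the root: every age scales by backbone/root
  nwk2 <- "((E1:1,S1:1):1,E2:2);"
  resc2 <- rescale_subtree(read_tree(text = nwk2),
                           list(task_id = "h", exemplars = c("E1", "E2"),
                                calibration_age = 10))
  expect_equal(max(node_ages(resc2)), 10)
  expect_error(rescale_subtree(read_tree(text = "((E1:0,E2:0):1,S1:1);"),
                               list(task_id = "z", exemplars = c("E1", "E2"),
                                    calibration_age = 5)),
               "age 0")
})

test_that("grafting shortens the stem by the excess subtree depth", {
  # backbone: exemplar cherry (E1,E2) at age 5, stem to age 11 (length 6)
  bb <- read_tree(text = "((E1:5,E2:5):6,(O1:8,O2:8):3);")
  # rescaled subtree: exemplar MRCA at 5, root at 10 => d = 5
  sub <- read_tree(text = "(((E1:5,E2:5):3,S1:8):2,S2:10);")
  task <- list(task_id = "g", exemplars = c("E1", "E2"), calibration_age = 5)
  out <- graft_subtree(bb, sub, task)
  validate_chronogram(out)
  ages <- node_ages(out)
  expect_setequal(out$phy$tip.label, c("E1", "E2", "S1", "S2", "O1", "O2"))
  sub_root <- ape::getMRCA(out$phy, c("E1", "S2"))
  expect_equal(ages[sub_root], 10)                 # subtree root age kept
  parent <- out$phy$edge[out$phy$edge[, 2] == sub_root, 1]
  expect_equal(ages[parent] - ages[sub_root], 1)   # stem 6 - d 5 = 1
  expect_equal(ages[ape::getMRCA(out$phy, c("E1", "E2"))], 5)
  expect_equal(ages[ape::getMRCA(out$phy, c("O1", "O2"))], 8)  # untouched

  # stem 3 < d = 5: negative branch error naming the clade
  bb2 <- read_tree(text = "((E1:5,E2:5):3,(O1:6,O2:6):2);")
  expect_error(graft_subtree(bb2, sub, task), "negative branch.*g")
  # clamp mode completes with a diagnostic instead
  expect_warning(out2 <- graft_subtree(bb2, sub, task, mode = "clamp"),
                 "clamped")
  validate_chronogram(out2)

  # exemplars spanning the subtree root with equal ages: stem untouched
  sub3 <- read_tree(text = "((E1:4,S1:4):1,E2:5);")
  out3 <- graft_subtree(bb, sub3, list(task_id = "g",
                                       exemplars = c("E1", "E2"),
                                       calibration_age = 5))
  ages3 <- node_ages(out3)
  expect_equal(ages3[ape::getMRCA(out3$phy, c("E1", "E2"))], 5)
  expect_equal(max(ages3), 11)                     # backbone ages unchanged
  expect_equal(ape::Ntip(out3$phy), 4 + 1)         # one new tip (S1)
})

test_that("graft_all applies disjoint grafts deepest-first", {
  bb <- read_tree(text = "((E1:5,E2:5):6,(F1:8,F2:8):3);")
  t1 <- list(task_id = "g1", exemplars = c("E1", "E2"), calibration_age = 5)
  t2 <- list(task_id = "g2", exemplars = c("F1", "F2"), calibration_age = 8)
  # exemplars span each subtree root, so rescaling pins the roots to the
  # backbone ages and the stems stay untouched
  s1 <- rescale_subtree(read_tree(text = "((E1:5,X1:5):1,E2:6);"), t1)
  s2 <- rescale_subtree(read_tree(text = "((F1:8,Y1:8):1,F2:9);"), t2)
  out <- graft_all(bb, list(s1, s2), list(t1, t2))
  validate_chronogram(out)
  expect_equal(ape::Ntip(out$phy), 4 - 4 + 3 + 3)
  ages <- node_ages(out)
  expect_equal(ages[ape::getMRCA(out$phy, c("E1", "E2"))], 5)
  expect_equal(ages[ape::getMRCA(out$phy, c("F1", "F2"))], 8)

  # zero tasks: backbone unchanged
  out0 <- graft_all(bb, list(), list())
  expect_equal(write_tree(out0), write_tree(as_chronogram(bb)))

  # a failing graft names the clade
  s_bad <- read_tree(text = "((E1:5,X1:5):20,E2:25);")
  expect_error(graft_all(bb, list(s_bad, s2), list(t1, t2)),
               "graft failed for task g1")
})
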