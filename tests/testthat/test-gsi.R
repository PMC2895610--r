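test_that("Newick reading validates structure and allows polytomies", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  poly <- read_newick("((A,B,C),D);")
  expect_equal(max(tabulate(poly$edge[, 1])), 3)
  expect_error(read_newick("((A,B),(C,A));"), "duplicate")
  ## file round trip preserves topology
  set.seed(41)
  for (b in 1:20) {
    t0 <- ape::rtree(sample(5:15, 1))
    f <- tempfile(fileext = ".nwk")
    write_newick(t0, f)
    expect_true(ape::all.equal.phylo(read_newick(f), t0,
                                     use.edge.length = FALSE))
  }
})

test_that("neighbor joining recovers additive topologies and roots", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["C", "D"] <- 7; d["A", "C"] <- 5
  d["A", "D"] <- 6; d["B", "C"] <- 6; d["B", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining(d)
  expect_true(ape::is.monophyletic(tr, c("A", "B")) ||
              ape::is.monophyletic(tr, c("C", "D")))
  tro <- neighbor_joining(d, "outgroup", outgroup = "D")
  expect_true(ape::is.monophyletic(tro, c("A", "B", "C")))
  ## NJ on true-genealogy distances recovers deep species monophyly
  sc <- coalescent_scenario(n_per_pop = c(8, 8), theta0 = 1, theta1 = 1,
                            tau_expansion = 0, t_div_years = 1e6,
                            mu_site_per_gen = 1e-9, L = 500)
  sim <- simulate_two_population(sc, seed = 55)
  dd <- ape::cophenetic.phylo(sim$genealogy)
  njt <- neighbor_joining(dd)
  expect_true(ape::is.monophyletic(njt, grep("^A", njt$tip.label,
                                             value = TRUE)))
})

test_that("gsi anchors: monophyly and whole-tree give exactly 1", {
  set.seed(61)
  for (b in 1:30) {
    tr <- ape::rtree(sample(8:20, 1))
    ## a random proper clade
    internal <- unique(tr$edge[, 1])
    node <- sample(setdiff(internal, ape::Ntip(tr) + 1), 1)
    clade <- ape::extract.clade(tr, node)$tip.label
    if (length(clade) < 2 || length(clade) >= ape::Ntip(tr)) next
    expect_identical(gsi(tr, clade)$gsi, 1)
  }
  tr <- ape::rtree(12)
  expect_equal(gsi(tr, tr$tip.label)$gsi, 1)
  expect_equal(gsi_test(tr, tr$tip.label, 99)$p, 1)
  expect_error(gsi(tr, c("t1", "nope")), "label error")
})

test_that("gsi matches an independent path-based transcription", {
  ## 8-tip caterpillar with maximally interleaved group
  cat8 <- read_newick("(((((((A,B),C),D),E),F),G),H);")
  grp <- c("A", "C", "E", "G")
  r <- gsi(cat8, grp)
  expect_equal(r$gsi, brute_gsi(cat8, grp), tolerance = 1e-12)
  set.seed(71)
  for (b in 1:40) {
    tr <- ape::rtree(sample(6:18, 1))
    k <- sample(2:(ape::Ntip(tr) - 1), 1)
    grp <- sample(tr$tip.label, k)
    expect_equal(gsi(tr, grp)$gsi, brute_gsi(tr, grp), tolerance = 1e-12,
                 label = paste("tree rep", b))
  }
})

test_that("gsi is invariant to non-group relabeling and child order", {
  set.seed(81)
  tr <- ape::rtree(14)
  grp <- sample(tr$tip.label, 6)
  base <- gsi(tr, grp)$gsi
  tr2 <- tr
  others <- setdiff(tr2$tip.label, grp)
  tr2$tip.label[match(others, tr2$tip.label)] <- sample(others)
  expect_equal(gsi(tr2, grp)$gsi, base)
  tr3 <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_equal(gsi(tr3, grp)$gsi, base)
})

test_that("deleting a non-group tip never decreases raw exclusivity", {
  ## the raw gs statistic is monotone under pruning of non-group tips on
  ## bifurcating trees (the uniting node set can only shrink); note the
  ## normalized gsi is not, because its dispersed floor (k-1)/(T-2) rises
  ## as the tree shrinks
  set.seed(91)
  for (b in 1:60) {
    tr <- ape::rtree(sample(8:16, 1))
    k <- sample(2:(ape::Ntip(tr) - 3), 1)
    grp <- sample(tr$tip.label, k)
    g0 <- gsi(tr, grp)$gs
    tr2 <- ape::drop.tip(tr, sample(setdiff(tr$tip.label, grp), 1))
    expect_gte(gsi(tr2, grp)$gs, g0 - 1e-9)
  }
})

test_that("gsi permutation test has power on monophyletic groups", {
  tr <- ape::stree(16, "balanced")
  grp <- tr$tip.label[1:8]
  r <- gsi_test(tr, grp, n_perm = 999, seed = 3)
  expect_equal(r$gsi, 1)
  expect_lte(r$p, 0.01)
})

test_that("balanced subsampling keeps allele copies together and prunes cleanly", {
  sc <- coalescent_scenario(n_per_pop = c(8, 16), theta1 = 2,
                            tau_expansion = 0, t_div_years = 20600)
  sim <- simulate_two_population(sc, seed = 91)
  ## treat consecutive tip pairs as the two allele copies of one individual
  meta <- sim$aln$meta
  meta$individual_id <- paste0("i", rep(seq_len(12), each = 2))
  gb <- gsi_balanced(sim$genealogy, meta, "species", n_subsamples = 8,
                     n_perm = 0, seed = 5)
  expect_equal(gb$n_individuals_per_group, 4)
  for (tips in gb$kept_tips) {
    inds <- meta$individual_id[match(tips, meta$sample_id)]
    expect_true(all(table(inds) == 2))     # never split an individual
    expect_equal(length(tips), 16)
  }
  expect_equal(nrow(gb$per_subsample), 16)
  expect_true(all(gb$per_subsample$gsi >= 0 & gb$per_subsample$gsi <= 1))
  ## already balanced input: every subsample keeps all individuals
  sc2 <- coalescent_scenario(n_per_pop = c(6, 6), theta1 = 2,
                             tau_expansion = 0)
  sim2 <- simulate_two_population(sc2, seed = 92)
  gb2 <- gsi_balanced(sim2$genealogy, sim2$aln$meta, "species",
                      n_subsamples = 3, seed = 1)
  expect_true(all(vapply(gb2$kept_tips, length, 1L) == 12))
  expect_equal(length(unique(gb2$per_subsample$gsi[gb2$per_subsample$group == "A"])), 1)
})
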