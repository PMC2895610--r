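## shared 2 groups x 2 populations x 3 samples fixture with a specified
## integer distance matrix (built from haplotypes so it is realisable)
amova_fixture <- function() {
  seqs <- c("AAAAAA", "AAAAAT", "AAAATT",    # pop p1 (group g1)
            "AATTTT", "AATTTA", "AATTAA",    # pop p2 (group g1)
            "TTTTAA", "TTTTAT", "TTTTTT",    # pop q1 (group g2)
            "TTAAAA", "TTAATA", "TTAATT")    # pop q2 (group g2)
  pop <- rep(c("p1", "p2", "q1", "q2"), each = 3)
  grp <- rep(c("g1", "g2"), each = 6)
  d <- pairwise_differences(make_aln(seqs, species = grp, population = pop))
  list(d = d, pop = pop, grp = grp)
}

test_that("degenerate and maximal-structure cases behave as defined", {
  ## all sequences identical: zero SS, undefined indices
  a <- make_aln(rep("ACGTACGT", 8),
                species = rep(c("x", "y"), each = 4),
                population = rep(c("p1", "p2", "q1", "q2"), each = 2))
  r <- amova(pairwise_differences(a), a$meta$population, a$meta$species)
  expect_equal(unname(r$SS["total"]), 0)
  expect_equal(unname(r$sigma2), c(0, 0, 0))
  expect_true(is.na(r$Phi_CT) && is.na(r$Phi_ST))
  ## two groups of one population each, fixed for distinct haplotypes
  b <- make_aln(rep(c("AAAA", "AATT"), each = 10),
                species = rep(c("x", "y"), each = 10),
                population = rep(c("p1", "q1"), each = 10))
  rb <- amova(pairwise_differences(b), b$meta$population, b$meta$species)
  expect_equal(unname(rb$sigma2[c("b", "c")]), c(0, 0))
  expect_equal(rb$Phi_CT, 1)
  ## maximal statistic: sample permutations essentially never reproduce the
  ## split, so Phi_ST's p sits at its attainable floor 1/(n_perm + 1);
  ## the whole-population permutation space here is the identity, so the
  ## Phi_CT p stays at 1 by construction
  p <- amova_significance(pairwise_differences(b), b$meta$population,
                          b$meta$species, n_perm = 99, seed = 1)
  expect_equal(unname(p["Phi_ST"]), 1 / 100)
  expect_equal(unname(p["Phi_CT"]), 1)
})

test_that("variance components equal the brute-force SS decomposition", {
  fx <- amova_fixture()
  r <- amova(fx$d, fx$pop, fx$grp)
  bf <- brute_amova(matrix(as.numeric(fx$d), nrow(fx$d)), fx$pop, fx$grp)
  expect_equal(unname(r$sigma2), unname(bf$sigma2), tolerance = 1e-9)
  expect_equal(unname(r$SS[1:3]), unname(bf$SS[1:3]), tolerance = 1e-9)
  expect_equal(r$Phi_CT, bf$Phi_CT, tolerance = 1e-9)
  expect_equal(r$Phi_SC, bf$Phi_SC, tolerance = 1e-9)
  expect_equal(r$Phi_ST, bf$Phi_ST, tolerance = 1e-9)
  expect_equal(sum(r$percent_variation), 100, tolerance = 1e-8)
})

test_that("total SS is permutation-invariant and p-values reproducible", {
  fx <- amova_fixture()
  obs <- idpopgen:::.amova_core(matrix(as.numeric(fx$d), 12),
                                match(fx$pop, unique(fx$pop)),
                                c(1L, 1L, 2L, 2L))
  set.seed(2)
  for (b in 1:10) {
    perm <- sample(12)
    d2p <- matrix(as.numeric(fx$d), 12)[perm, perm]
    r <- idpopgen:::.amova_core(d2p, match(fx$pop, unique(fx$pop)),
                                c(1L, 1L, 2L, 2L))
    expect_equal(unname(r$SS["total"]), unname(obs$SS["total"]))
  }
  p1 <- amova_significance(fx$d, fx$pop, fx$grp, n_perm = 99, seed = 7)
  p2 <- amova_significance(fx$d, fx$pop, fx$grp, n_perm = 99, seed = 7)
  expect_identical(p1, p2)
})

test_that("single-group design collapses to the classical two-level Phi_ST", {
  fx <- amova_fixture()
  r <- amova(fx$d, fx$pop, rep("one", 12))
  expect_true(is.na(r$Phi_CT))
  expect_equal(r$Phi_ST,
               brute_amova_two_level(matrix(as.numeric(fx$d), 12), fx$pop),
               tolerance = 1e-9)
})

test_that("scaling between-group distances cannot decrease Phi_CT", {
  fx <- amova_fixture()
  d2 <- matrix(as.numeric(fx$d), 12)
  base <- idpopgen:::.amova_core(d2, match(fx$pop, unique(fx$pop)),
                                 c(1L, 1L, 2L, 2L))$Phi_CT
  between <- outer(fx$grp, fx$grp, `!=`)
  for (c_scale in c(1.5, 3, 10)) {
    d2s <- d2
    d2s[between] <- d2s[between] * c_scale
    r <- idpopgen:::.amova_core(d2s, match(fx$pop, unique(fx$pop)),
                                c(1L, 1L, 2L, 2L))
    expect_gte(r$Phi_CT, base - 1e-12)
  }
})
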