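test_that("single-population simulator honours limits and determinism", {
  z <- simulate_single_population(0, 6, L = 50, seed = 3)
  expect_equal(length(unique(z$aln$seq)), 1)       # theta = 0: identical
  expect_s3_class(z$genealogy, "phylo")            # genealogy still returned
  a <- simulate_single_population(1.5, 12, L = 300, seed = 21)
  b <- simulate_single_population(1.5, 12, L = 300, seed = 21)
  expect_identical(a$aln$seq, b$aln$seq)           # byte-identical given seed
  c2 <- simulate_single_population(1.5, 12, L = 300, seed = 22)
  expect_false(identical(a$aln$seq, c2$aln$seq))
  expect_error(simulate_single_population(50, 40, L = 5, seed = 1),
               "site exhaustion")
})

test_that("mean pairwise diversity matches the coalescent expectation", {
  set.seed(101)
  B <- 400; theta <- 2; n <- 10
  pis <- vapply(seq_len(B), function(b) {
    d <- pairwise_differences(simulate_single_population(theta, n, L = 300)$aln)
    mean(d[upper.tri(d)])
  }, 0)
  se <- stats::sd(pis) / sqrt(B)
  expect_lt(abs(mean(pis) - theta), 3 * se)
})

test_that("expansion simulator reduces to stationary model at tau = 0 and
           peaks near tau otherwise", {
  sc0 <- coalescent_scenario(theta0 = 1.2, theta1 = 1.2, tau_expansion = 0,
                             L = 300)
  x <- simulate_expansion_population(sc0, n = 8, seed = 5)
  y <- simulate_single_population(1.2, 8, L = 300, seed = 5)
  expect_identical(x$aln$seq, y$aln$seq)    # same epochs, same draws
  ## pooled mismatch mode lies near tau under strong expansion
  set.seed(71)
  sc <- coalescent_scenario(theta0 = 1, theta1 = 1000, tau_expansion = 5,
                            L = 1500)
  pool <- integer(40)
  for (b in 1:60) {
    d <- pairwise_differences(simulate_expansion_population(sc, n = 25)$aln)
    v <- d[upper.tri(d)]
    pool <- pool + tabulate(pmin(v, 39) + 1L, 40)
  }
  expect_lte(abs(which.max(pool) - 1 - 5), 2)
})

test_that("two-population simulator produces the expected structure", {
  ## no divergence, shared deme sizes: Phi_CT centred on 0 over replicates
  set.seed(19)
  sc0 <- coalescent_scenario(n_per_pop = c(10, 10), theta0 = 2, theta1 = 2,
                             tau_expansion = 0, t_div_years = 0,
                             mig_rate = 0, L = 500)
  phis <- vapply(1:40, function(b) {
    sim <- simulate_two_population(sc0, n_pops_per_species = 2)
    d <- pairwise_differences(sim$aln)
    suppressWarnings(
      amova(d, sim$aln$meta$population, sim$aln$meta$species)$Phi_CT)
  }, 0)
  phis <- phis[!is.na(phis)]        # monomorphic replicates: Phi undefined
  expect_lt(abs(mean(phis)), 3 * stats::sd(phis) / sqrt(length(phis)))
  ## deep split, no migration: reciprocal monophyly on the true genealogy
  sc1 <- coalescent_scenario(n_per_pop = c(10, 10), theta0 = 1, theta1 = 1,
                             tau_expansion = 0, t_div_years = 2e6,
                             mig_rate = 0, mu_site_per_gen = 1e-9, L = 500)
  mono <- vapply(1:30, function(b) {
    g <- simulate_two_population(sc1)$genealogy
    ape::is.monophyletic(g, grep("^A", g$tip.label, value = TRUE)) &&
      ape::is.monophyletic(g, grep("^B", g$tip.label, value = TRUE))
  }, TRUE)
  expect_gte(mean(mono), 0.95)
})

test_that("true-genealogy gsi rises with divergence time at mig = 0", {
  set.seed(23)
  mean_gsi <- vapply(c(3000, 16000, 64000), function(tdiv) {
    mean(vapply(1:20, function(b) {
      sc <- coalescent_scenario(n_per_pop = c(10, 10), theta1 = 1,
                                tau_expansion = 0, t_div_years = tdiv,
                                mu_site_per_gen = 1e-8)
      g <- simulate_two_population(sc)$genealogy
      gsi(g, grep("^A", g$tip.label, value = TRUE))$gsi
    }, 0))
  }, 0)
  expect_true(all(diff(mean_gsi) > 0))
})

test_that("predation-trial generator follows the binomial model", {
  cells <- data.frame(prey_species = "parvula", treatment = "predator",
                      p_survive = 1)
  tr <- simulate_predation_trials(cells, n_reps = 10, seed = 2)
  expect_true(all(tr$P_T == tr$P_I))
  expect_equal(proportion_missing(tr$P_I, tr$P_T)$proportion, rep(0, 10))
  set.seed(13)
  cells$p_survive <- 0.5
  tr <- simulate_predation_trials(cells, P_I = 20, n_reps = 1000)
  se <- stats::sd(tr$P_T) / sqrt(1000)
  expect_lt(abs(mean(tr$P_T) - 10), 3 * se)
  t1 <- simulate_predation_trials(cells, n_reps = 5, seed = 8)
  t2 <- simulate_predation_trials(cells, n_reps = 5, seed = 8)
  expect_identical(t1$P_T, t2$P_T)
})
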