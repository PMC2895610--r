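test_that("alignment construction validates and normalizes input", {
  a <- make_aln(c("acgu", "ACGA"))
  expect_equal(a$length, 4)
  expect_equal(unname(a$seq[1]), "ACGT")   # uppercased, U -> T
  b <- make_aln(c("ACRT", "ACGT"))         # ambiguity codes become N
  expect_equal(unname(b$seq[1]), "ACNT")
  expect_error(make_aln(c("ACGT", "ACGTA")), "unequal lengths")
})

test_that("FASTA + metadata round-trips through write/read", {
  sim <- simulate_single_population(2, 8, L = 120, seed = 11)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_alignment(sim$aln, fa, tsv)
  back <- read_alignment(fa, tsv)
  expect_identical(back$seq, sim$aln$seq)
  expect_identical(back$meta, sim$aln$meta)
  ## mismatched metadata id is a join error
  meta2 <- sim$aln$meta
  meta2$sample_id[1] <- "nope"
  utils::write.table(meta2, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_alignment(fa, tsv), "join error")
})

test_that("haploid duplication doubles records and is invertible", {
  a <- make_aln(c("ACGT", "AGGT", "ACGA"))
  d <- duplicate_haploid_copies(a)
  expect_equal(length(d$seq), 6)
  expect_equal(length(unique(d$meta$individual_id)), 3)
  expect_setequal(unique(d$meta$allele_copy), c("a", "b"))
  ## collapsing back by individual gives the input sequences
  first <- !duplicated(d$meta$individual_id)
  expect_equal(unname(d$seq[first]), unname(a$seq))
  ## distances on duplicated data appear in 2x2 blocks
  pd <- pairwise_differences(d)
  for (i in 1:3) for (j in 1:3)
    expect_true(all(pd[2 * i - c(1, 0), 2 * j - c(1, 0)] ==
                    pd[2 * i, 2 * j] * (i != j)))
})

test_that("pairwise differences match the per-site brute-force counter", {
  expect_equal(unname(pairwise_differences(make_aln(c("ACGT", "ACGA")))[1, 2]), 1)
  pd <- pairwise_differences(make_aln(c("AC-T", "ACGT")))
  expect_equal(unname(pd[1, 2]), 0)
  expect_equal(attr(pd, "sites_used"), 3)
  expect_error(pairwise_differences(make_aln(c("----", "ACGT"))),
               "degenerate")
  set.seed(31)
  for (rep in 1:5) {
    seqs <- rand_seqs(10, 50, miss_p = 0.08)
    a <- make_aln(seqs)
    dc <- pairwise_differences(a, "complete_deletion")
    dp <- pairwise_differences(a, "pairwise_deletion")
    expect_equal(unclass(dc), brute_pairdiff(seqs, "complete"),
                 ignore_attr = TRUE)
    expect_equal(unclass(dp), brute_pairdiff(seqs, "pairwise"),
                 ignore_attr = TRUE)
    expect_true(all(dc <= attr(dc, "sites_used")))
    expect_true(all(attr(dp, "sites_used") <= 50))
    ## triangle inequality under complete deletion
    n <- nrow(dc)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(dc[i, j], dc[i, k] + dc[k, j])
  }
})

test_that("haplotype collapsing preserves counts and composition", {
  a <- make_aln(c("AAA", "AAA", "AAT"))
  h <- collapse_haplotypes(a)
  expect_equal(length(h$haplotypes), 2)
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(length(collapse_haplotypes(make_aln(rep("AAAA", 5)))$haplotypes), 1)
  ## expanding by assignment reproduces the multiset of sequences
  set.seed(5)
  seqs <- sample(c("AAAA", "AATA", "TTTT"), 20, replace = TRUE)
  sp <- sample(c("x", "y"), 20, replace = TRUE)
  pop <- sample(c("p1", "p2", "p3"), 20, replace = TRUE)
  a <- make_aln(seqs, species = sp, population = pop)
  h <- collapse_haplotypes(a)
  expect_identical(unname(h$haplotypes[h$assignment]), unname(a$seq))
  expect_equal(sum(h$composition), 20)
  expect_equal(as.vector(rowSums(h$composition)), h$counts)
})

test_that("group balancing keeps whole individuals and is seed-deterministic", {
  seqs <- rand_seqs(28, 10)
  ind <- rep(sprintf("i%02d", 1:14), each = 2)
  sp <- rep(c("parvula", "retrocurva"), c(8, 20))
  a <- make_aln(seqs, species = sp, population = "p1", individual = ind,
                copy = rep(c("a", "b"), 14))
  b <- balance_groups(a, "species", seed = 9)
  expect_equal(as.vector(table(b$meta$species)), c(4L, 4L) * 2L)
  ## both allele copies kept together
  expect_true(all(table(b$meta$individual_id) == 2))
  b2 <- balance_groups(a, "species", seed = 9)
  expect_identical(b$meta$sample_id, b2$meta$sample_id)
  ## already balanced input is returned with the same individuals
  bal <- balance_groups(b, "species", seed = 1)
  expect_setequal(bal$meta$individual_id, b$meta$individual_id)
})
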