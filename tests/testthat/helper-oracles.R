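# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately avoid the package's own code paths.

make_aln <- function(seqs, species = "sp", population = "p1",
                     marker = "ND2", individual = NULL, copy = "a") {
  n <- length(seqs)
  if (is.null(individual)) individual <- sprintf("ind%02d", seq_len(n))
  meta <- data.frame(
    sample_id = sprintf("%s_%s", individual, rep_len(copy, n)),
    individual_id = individual,
    species = rep_len(species, n),
    population = rep_len(population, n),
    marker = rep_len(marker, n),
    allele_copy = rep_len(copy, n),
    stringsAsFactors = FALSE)
  labeled_alignment(seqs, meta)
}

rand_seqs <- function(n, L, miss_p = 0) {
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    s <- sample(alphabet, L, replace = TRUE)
    if (miss_p > 0) {
      idx <- which(stats::runif(L) < miss_p)
      s[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
    }
    paste(s, collapse = "")
  }, "")
}

# per-site brute-force pairwise difference counter
brute_pairdiff <- function(seqs, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  ch <- lapply(strsplit(seqs, ""), function(x) {
    x[x %in% c("-", "N")] <- NA
    x
  })
  n <- length(ch)
  if (policy == "complete") {
    bad <- Reduce(`|`, lapply(ch, is.na))
    ch <- lapply(ch, function(x) x[!bad])
  }
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(ch[[i]]) & !is.na(ch[[j]])
    d[i, j] <- sum(ch[[i]][ok] != ch[[j]][ok])
  }
  d
}

# independent transcription of the genealogical sorting index using ape
# path utilities (no parent-pointer climbing)
brute_gsi <- function(tree, group) {
  k <- length(group)
  ntip <- length(tree$tip.label)
  if (k == 1 || k == ntip) return(1)
  tips <- match(group, tree$tip.label)
  mrca <- ape::getMRCA(tree, group)
  nodes <- unique(unlist(lapply(tips, function(tp)
    ape::nodepath(tree, from = tp, to = mrca))))
  nodes <- nodes[nodes > ntip]
  root <- ntip + 1L
  deg <- vapply(nodes, function(v)
    sum(tree$edge[, 1] == v) + as.integer(v != root), 0L)
  gs <- (k - 1) / sum(deg - 2)
  gs_min <- (k - 1) / (ntip - 2)
  if (gs_min >= 1) 1 else (gs - gs_min) / (1 - gs_min)
}

# independent three-level AMOVA SS decomposition by explicit pair loops
brute_amova <- function(d2, pop, grp) {
  N <- nrow(d2)
  pair_sum <- function(idx) {
    s <- 0
    if (length(idx) >= 2)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
    s
  }
  SS_total <- pair_sum(seq_len(N)) / N
  pops <- unique(pop)
  grps <- unique(grp)
  SS_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    pair_sum(idx) / length(idx)
  }, 0))
  SS_wg <- sum(vapply(grps, function(g) {
    idx <- which(grp == g)
    pair_sum(idx) / length(idx)
  }, 0))
  SS_ag <- SS_total - SS_wg
  SS_ap <- SS_wg - SS_wp
  P <- length(pops); G <- length(grps)
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  names(n_p) <- pops
  n_g <- vapply(grps, function(g) sum(grp == g), 0)
  sum_np2_over_ng <- sum(vapply(grps, function(g) {
    sum(n_p[pops %in% unique(pop[grp == g])]^2) / sum(grp == g)
  }, 0))
  n1 <- (N - sum_np2_over_ng) / (P - G)
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  s_c <- SS_wp / (N - P)
  s_b <- (SS_ap / (P - G) - s_c) / n1
  s_a <- (SS_ag / (G - 1) - s_c - n2 * s_b) / n3
  list(sigma2 = c(a = s_a, b = s_b, c = s_c),
       SS = c(AG = SS_ag, AP = SS_ap, WP = SS_wp, total = SS_total),
       Phi_CT = s_a / (s_a + s_b + s_c),
       Phi_SC = s_b / (s_b + s_c),
       Phi_ST = (s_a + s_b) / (s_a + s_b + s_c))
}

# classical two-level AMOVA Phi_ST oracle (populations only)
brute_amova_two_level <- function(d2, pop) {
  N <- nrow(d2)
  pair_sum <- function(idx) {
    s <- 0
    if (length(idx) >= 2)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
    s
  }
  pops <- unique(pop)
  P <- length(pops)
  n_p <- vapply(pops, function(p) sum(pop == p), 0)
  SS_total <- pair_sum(seq_len(N)) / N
  SS_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    pair_sum(idx) / length(idx)
  }, 0))
  SS_ap <- SS_total - SS_wp
  nc <- (N - sum(n_p^2) / N) / (P - 1)
  s_w <- SS_wp / (N - P)
  s_a <- (SS_ap / (P - 1) - s_w) / nc
  s_a / (s_a + s_w)
}

# minimum spanning tree total weight by exhaustive enumeration of
# spanning trees (feasible for <= 6 nodes)
brute_mst_weight <- function(d) {
  n <- nrow(d)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  best <- Inf
  for (sel in utils::combn(nrow(pr), n - 1, simplify = FALSE)) {
    comp <- seq_len(n)
    for (e in sel) {
      a <- comp[pr[e, 1]]; b <- comp[pr[e, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1L) best <- min(best, sum(w[sel]))
  }
  best
}
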