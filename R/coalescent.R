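#' Demographic scenario for the coalescent generators
#'
#' Collects every parameter of the two-population
#' isolation-with-migration-plus-expansion history under which synthetic
#' data are generated. Defaults describe the mitochondrial (ND2) study
#' conditions: two species sampled 20 gene copies each, no migration,
#' divergence 20,600 years ago, a sudden post-glacial expansion at
#' mutational age tau, and the per-year substitution rate paired with its
#' per-generation equivalent at five generations per year. The per-year and
#' per-generation rates are carried explicitly and never reconciled; see the
#' methods vignette.
#'
#' @param n_per_pop Integer vector of sample sizes (gene copies) per
#'   population/species.
#' @param theta0 Pre-expansion scaled diversity per sequence (2*N0*u).
#' @param theta1 Post-expansion scaled diversity per sequence; may be `Inf`.
#' @param tau_expansion Scaled expansion age in mutational units (2*u*t
#'   generations); the size change sits at scaled time `tau_expansion/2`.
#' @param t_div_years Species divergence time in years.
#' @param mig_rate Migrants per generation exchanged between the demes.
#' @param mu_site_per_gen Mutation rate per site per generation (used to
#'   place mutations in generation-time simulations).
#' @param mu_site_per_year Mutation rate per site per year (used by the
#'   divergence-time estimator).
#' @param L Sequence length in bp.
#' @param gens_per_year Generations per year.
#' @param seed Optional integer seed recorded with the scenario.
#' @return A list of class `coalescent_scenario`.
#' @export
coalescent_scenario <- function(n_per_pop = c(20, 20),
                                theta0 = 1,
                                theta1 = 1000,
                                tau_expansion = 4.765,
                                t_div_years = 20600,
                                mig_rate = 0,
                                mu_site_per_gen = 6.6e-7,
                                mu_site_per_year = 3.3e-6,
                                L = 631,
                                gens_per_year = 5,
                                seed = NULL) {
  stopifnot(all(n_per_pop >= 0), theta0 >= 0, theta1 >= 0,
            tau_expansion >= 0, t_div_years >= 0, mig_rate >= 0,
            mu_site_per_gen >= 0, mu_site_per_year >= 0,
            L >= 1, gens_per_year > 0)
  structure(list(n_per_pop = as.integer(n_per_pop), theta0 = theta0,
                 theta1 = theta1, tau_expansion = tau_expansion,
                 t_div_years = t_div_years, mig_rate = mig_rate,
                 mu_site_per_gen = mu_site_per_gen,
                 mu_site_per_year = mu_site_per_year, L = as.integer(L),
                 gens_per_year = gens_per_year, seed = seed),
            class = "coalescent_scenario")
}

## Discrete-deme structured coalescent, piecewise-constant deme sizes.
## epochs: list of list(end, N = deme sizes, mig = per-lineage backward
## migration rate per deme, collapse = move all lineages to deme 1 on entry).
## Time units are whatever the caller uses (generations or mutational time);
## pairwise coalescence rate within a deme is 1/N per unit time, so that a
## stationary deme yields E(pairwise difference) = 2*N*u = theta.
## Returns parent pointers and node times (tips 1..n, internals n+1..2n-1).
.sim_genealogy <- function(n_per_deme, epochs) {
  n <- sum(n_per_deme)
  if (n < 2) stop("need at least 2 sampled sequences")
  parent <- integer(2L * n - 1L)
  ntime <- numeric(2L * n - 1L)
  deme_of <- rep(seq_along(n_per_deme), n_per_deme)
  active <- seq_len(n)           # node ids of live lineages
  lin_deme <- deme_of            # deme per live lineage
  nxt <- n + 1L
  t <- 0
  ei <- 1L
  while (length(active) > 1L) {
    ep <- epochs[[ei]]
    nd <- length(ep$N)
    if (nd == 1L && any(lin_deme != 1L)) lin_deme[] <- 1L
    k <- tabulate(lin_deme, nd)
    ## a deme of size zero coalesces everything it holds instantly
    zero <- which(ep$N == 0 & k >= 2L)
    if (length(zero)) {
      for (d in zero) {
        while (sum(lin_deme == d) >= 2L && length(active) > 1L) {
          pick <- which(lin_deme == d)[1:2]
          parent[active[pick]] <- nxt
          ntime[nxt] <- t
          active <- c(active[-pick], nxt)
          lin_deme <- c(lin_deme[-pick], d)
          nxt <- nxt + 1L
        }
      }
      next
    }
    coal <- ifelse(is.finite(ep$N) & k >= 2L, choose(k, 2) / ep$N, 0)
    migr <- k * ep$mig
    total <- sum(coal) + sum(migr)
    if (total <= 0) {
      if (!is.finite(ep$end))
        stop("degenerate scenario: no events possible and epoch unbounded")
      t <- ep$end
      ei <- ei + 1L
      next
    }
    dt <- stats::rexp(1L, total)
    if (t + dt >= ep$end) {
      t <- ep$end
      ei <- ei + 1L
      next
    }
    t <- t + dt
    ev <- sample.int(2L * nd, 1L, prob = c(coal, migr))
    if (ev <= nd) {                       # coalescence in deme ev
      pick <- sample(which(lin_deme == ev), 2L)
      parent[active[pick]] <- nxt
      ntime[nxt] <- t
      active <- c(active[-pick], nxt)
      lin_deme <- c(lin_deme[-pick], ev)
      nxt <- nxt + 1L
    } else {                              # migration out of deme ev - nd
      d <- ev - nd
      pick <- sample(which(lin_deme == d), 1L)
      lin_deme[pick] <- if (nd == 2L) 3L - d else d
    }
  }
  list(parent = parent, time = ntime, n = n)
}

.genealogy_newick <- function(gen, tip_labels) {
  n <- gen$n
  kids <- split(seq_len(2L * n - 1L)[gen$parent > 0L],
                gen$parent[gen$parent > 0L])
  lab <- function(v) {
    if (v <= n)
      paste0(tip_labels[v], ":",
             format(gen$time[gen$parent[v]] - gen$time[v], digits = 10))
    else {
      blen <- if (gen$parent[v] > 0L)
        gen$time[gen$parent[v]] - gen$time[v] else 0
      paste0("(", paste(vapply(kids[[as.character(v)]], lab, ""),
                        collapse = ","),
             "):", format(blen, digits = 10))
    }
  }
  root <- which(gen$parent == 0L)
  paste0(sub(":[^:]*$", "", lab(root)), ";")
}

## Place infinite-sites mutations on the genealogy and build tip sequences.
## u_seq: mutation rate per sequence per unit of the genealogy's time scale.
.mutate_genealogy <- function(gen, u_seq, L, tip_labels) {
  n <- gen$n
  has_parent <- which(gen$parent > 0L)
  blen <- gen$time[gen$parent[has_parent]] - gen$time[has_parent]
  nmut <- stats::rpois(length(blen), blen * u_seq)
  total <- sum(nmut)
  if (total > L)
    stop("site exhaustion: ", total, " mutations requested on ", L,
         " sites; increase L for this scenario")
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mut_site <- vector("list", 2L * n - 1L)
  mut_base <- vector("list", 2L * n - 1L)
  if (total > 0L) {
    sites <- sample.int(L, total)
    edge_of <- rep(has_parent, nmut)
    bases <- c("A", "C", "G", "T")
    derived <- vapply(sites, function(s)
      sample(setdiff(bases, anc[s]), 1L), "")
    mut_site[has_parent] <- split(sites, factor(edge_of, levels = has_parent))
    mut_base[has_parent] <- split(derived, factor(edge_of, levels = has_parent))
  }
  seqs <- character(n)
  for (tip in seq_len(n)) {
    s <- anc
    v <- tip
    while (v != 0L) {        # infinite sites: application order is immaterial
      if (length(mut_site[[v]])) s[mut_site[[v]]] <- mut_base[[v]]
      v <- gen$parent[v]
    }
    seqs[tip] <- paste(s, collapse = "")
  }
  names(seqs) <- tip_labels
  seqs
}

## pairwise difference counts of an expansion-history coalescent sample
## under ideal infinite sites, in mutational time (u_seq = 1): mutation
## counts are drawn per branch and differences read off the genealogy
## without materializing sequences. Used by the SSD bootstrap, where the
## null model itself assumes infinite sites.
.sim_pair_diffs <- function(theta0, theta1, tau, n) {
  epochs <- if (tau > 0)
    list(list(end = tau / 2, N = theta1 / 2, mig = 0),
         list(end = Inf, N = theta0 / 2, mig = 0))
  else list(list(end = Inf, N = theta0 / 2, mig = 0))
  gen <- .sim_genealogy(n, epochs)
  has_parent <- which(gen$parent > 0L)
  blen <- gen$time[gen$parent[has_parent]] - gen$time[has_parent]
  nmut <- stats::rpois(length(blen), blen)
  D <- matrix(0L, n, n)
  if (any(nmut > 0L)) {
    below <- vector("list", 2L * n - 1L)
    below[seq_len(n)] <- seq_len(n)
    kids <- split(seq_len(2L * n - 1L)[gen$parent > 0L],
                  gen$parent[gen$parent > 0L])
    for (v in (n + 1L):(2L * n - 1L))    # ids are in coalescence order
      below[[v]] <- unlist(below[kids[[as.character(v)]]],
                           use.names = FALSE)
    for (e in which(nmut > 0L)) {
      v <- has_parent[e]
      idx <- below[[v]]
      D[idx, -idx] <- D[idx, -idx] + nmut[e]
    }
    D <- D + t(D)      # each separating edge was added on one side only
  }
  D[upper.tri(D)]
}

.sim_meta <- function(tip_labels, species, population, marker = "sim") {
  data.frame(sample_id = tip_labels, individual_id = tip_labels,
             species = species, population = population, marker = marker,
             allele_copy = "a", stringsAsFactors = FALSE)
}

#' Simulate a standard neutral single-population coalescent sample
#'
#' Kingman coalescent in mutational time units with infinite-sites
#' mutation: branch lengths are expected mutations per sequence, a
#' stationary population of scaled diversity `theta` has pairwise
#' coalescence rate `2/theta`, and the expected mean pairwise difference
#' equals `theta`.
#'
#' @param theta Scaled diversity per sequence (2*N*u); `0` yields identical
#'   sequences (the genealogy is still returned, with zero branch lengths).
#' @param n Sample size (>= 2).
#' @param L Sequence length in bp; mutations occupy distinct sites, and the
#'   simulation errors out if more than `L` mutations are requested.
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @return List with `aln` (a [labeled_alignment()]) and `genealogy`
#'   (an [ape::read.tree()] `phylo`, branch lengths in mutational units).
#' @export
simulate_single_population <- function(theta, n, L = 1000, seed = NULL) {
  stopifnot(theta >= 0, n >= 2, L >= 1)
  with_seed(seed, {
    gen <- .sim_genealogy(n, list(list(end = Inf, N = theta / 2, mig = 0)))
    tips <- sprintf("s%03d", seq_len(n))
    seqs <- .mutate_genealogy(gen, 1, L, tips)
    list(aln = labeled_alignment(seqs, .sim_meta(tips, "A", "pop1")),
         genealogy = ape::read.tree(text = .genealogy_newick(gen, tips)))
  })
}

#' Simulate a coalescent sample under a sudden demographic expansion
#'
#' Stepwise size change in mutational time: scaled diversity `theta1`
#' after the expansion (towards the present) and `theta0` before it, with
#' the change at scaled time `tau_expansion/2` in the past. With
#' `tau_expansion = 0` this reduces to [simulate_single_population()] at
#' `theta0`.
#'
#' @param scenario A [coalescent_scenario()] supplying `theta0`, `theta1`
#'   (may be `Inf`), `tau_expansion` and `L`.
#' @param n Sample size; defaults to `sum(scenario$n_per_pop)`.
#' @param seed Optional integer seed.
#' @return As [simulate_single_population()].
#' @export
simulate_expansion_population <- function(scenario, n = NULL, seed = NULL) {
  if (is.null(n)) n <- sum(scenario$n_per_pop)
  stopifnot(scenario$theta1 >= scenario$theta0)
  with_seed(seed, {
    tau <- scenario$tau_expansion
    epochs <- if (tau > 0)
      list(list(end = tau / 2, N = scenario$theta1 / 2, mig = 0),
           list(end = Inf, N = scenario$theta0 / 2, mig = 0))
    else list(list(end = Inf, N = scenario$theta0 / 2, mig = 0))
    gen <- .sim_genealogy(n, epochs)
    tips <- sprintf("s%03d", seq_len(n))
    seqs <- .mutate_genealogy(gen, 1, scenario$L, tips)
    list(aln = labeled_alignment(seqs, .sim_meta(tips, "A", "pop1")),
         genealogy = ape::read.tree(text = .genealogy_newick(gen, tips)))
  })
}

#' Simulate a two-species isolation(-with-migration) coalescent sample
#'
#' Structured coalescent in generation time: two demes exchanging
#' `mig_rate` migrants per generation merge into a single ancestral deme
#' `t_div_years * gens_per_year` generations in the past. Each deme
#' optionally carries the stepwise expansion of the scenario (size
#' `theta1/(2u)` after the expansion, `theta0/(2u)` before it and in the
#' ancestor, with `u = mu_site_per_gen * L` per sequence per generation).
#' Mutations follow the infinite-sites model at rate `mu_site_per_gen`.
#'
#' @param scenario A [coalescent_scenario()].
#' @param seed Optional integer seed.
#' @param n_pops_per_species Number of population labels to distribute the
#'   samples of each species over (round robin). The labels partition the
#'   sample for hierarchical analyses; they carry no additional structure.
#' @return List with `aln` (species labels `A`/`B` in the metadata) and
#'   `genealogy` (branch lengths in generations).
#' @export
simulate_two_population <- function(scenario, seed = NULL,
                                    n_pops_per_species = 1L) {
  stopifnot(length(scenario$n_per_pop) == 2L, all(scenario$n_per_pop >= 2L))
  u_seq <- scenario$mu_site_per_gen * scenario$L
  if (u_seq <= 0) stop("mu_site_per_gen * L must be positive")
  N0 <- scenario$theta0 / (2 * u_seq)
  N1 <- scenario$theta1 / (2 * u_seq)
  t_div <- scenario$t_div_years * scenario$gens_per_year
  t_exp <- scenario$tau_expansion / (2 * u_seq)
  m0 <- if (is.finite(N0) && N0 > 0) scenario$mig_rate / N0 else 0
  m1 <- if (is.finite(N1) && N1 > 0) scenario$mig_rate / N1 else 0
  expanding <- scenario$tau_expansion > 0 && scenario$theta1 != scenario$theta0
  epochs <- list()
  if (expanding && t_exp < t_div) {
    epochs <- list(list(end = t_exp, N = c(N1, N1), mig = c(m1, m1)),
                   list(end = t_div, N = c(N0, N0), mig = c(m0, m0)))
  } else if (expanding) {
    ## expansion predates divergence: demes stay at the post-expansion size
    ## until they merge, the ancestor is at the pre-expansion size
    epochs <- list(list(end = t_div, N = c(N1, N1), mig = c(m1, m1)))
  } else {
    epochs <- list(list(end = t_div, N = c(N0, N0), mig = c(m0, m0)))
  }
  epochs <- c(epochs, list(list(end = Inf, N = N0, mig = 0)))
  with_seed(seed, {
    gen <- .sim_genealogy(scenario$n_per_pop, epochs)
    n <- sum(scenario$n_per_pop)
    species <- rep(c("A", "B"), scenario$n_per_pop)
    tips <- sprintf("%s%03d", species, c(seq_len(scenario$n_per_pop[1]),
                                         seq_len(scenario$n_per_pop[2])))
    pop <- paste0(species, rep_len(seq_len(max(1L, n_pops_per_species)),
                                   n))
    seqs <- .mutate_genealogy(gen, u_seq, scenario$L, tips)
    list(aln = labeled_alignment(seqs, .sim_meta(tips, species, pop)),
         genealogy = ape::read.tree(text = .genealogy_newick(gen, tips)))
  })
}

#' Simulate predation-trial count tables
#'
#' Final prey counts are Binomial(`P_I`, survival probability),
#' independently per replicate, per species-by-treatment cell. Defaults
#' mirror the invertebrate trial design: 20 adult prey per cup, one
#' predator (or none in controls), 24-hour trials.
#'
#' @param p_survive_by_cell Data frame with columns `prey_species`,
#'   `treatment` (`"control"`/`"predator"`) and `p_survive` in `[0, 1]`;
#'   an optional `n_reps` column overrides the default replicate count.
#' @param P_I Initial prey count per experimental unit.
#' @param X Predators per experimental unit in the predator treatment
#'   (controls get 0).
#' @param T_hours Trial duration in hours.
#' @param n_reps Replicates per cell (recycled over rows of
#'   `p_survive_by_cell` when no `n_reps` column is given).
#' @param seed Optional integer seed.
#' @return Data frame of class `predation_trials` with one row per trial:
#'   `prey_species`, `treatment`, `P_I`, `P_T`, `X`, `T_hours`.
#' @export
simulate_predation_trials <- function(p_survive_by_cell, P_I = 20, X = 1,
                                      T_hours = 24, n_reps = 20,
                                      seed = NULL) {
  cells <- as.data.frame(p_survive_by_cell, stringsAsFactors = FALSE)
  stopifnot(all(c("prey_species", "treatment", "p_survive") %in% names(cells)),
            all(cells$p_survive >= 0 & cells$p_survive <= 1),
            P_I >= 1, X >= 0, T_hours > 0)
  if (is.null(cells$n_reps)) cells$n_reps <- rep_len(n_reps, nrow(cells))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      r <- cells[i, ]
      data.frame(prey_species = r$prey_species, treatment = r$treatment,
                 P_I = P_I,
                 P_T = stats::rbinom(r$n_reps, P_I, r$p_survive),
                 X = if (r$treatment == "control") 0 else X,
                 T_hours = T_hours, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("predation_trials", "data.frame")
    out
  })
}
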