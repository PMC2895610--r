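## Core three-level AMOVA decomposition from a matrix of squared
## pairwise distances (for haplotype data the number of differing sites
## IS the squared Euclidean distance between sequences).
## pop: integer population per sample (1..P); gop: integer group per
## population (1..G). Unbalanced-design coefficients follow the
## Excoffier-Smouse-Quattro mean-square expectations.
.amova_core <- function(d2, pop, gop) {
  N <- nrow(d2)
  P <- length(gop)
  G <- length(unique(gop))
  fpop <- factor(pop, levels = seq_len(P))
  M <- rowsum(d2, fpop)
  TT <- rowsum(t(M), fpop)              # P x P pair-sum blocks
  n_p <- tabulate(pop, P)
  n_g <- as.numeric(tapply(n_p, gop, sum))
  within_p <- diag(TT) / 2
  SS_WP <- sum(ifelse(n_p > 0, within_p / pmax(n_p, 1), 0))
  gidx <- split(seq_len(P), gop)
  S_g <- vapply(gidx, function(ix) sum(TT[ix, ix]) / 2, 0)
  SS_wg <- sum(S_g / n_g)               # total SS within groups
  SS_total <- sum(d2) / (2 * N)
  SS_AG <- SS_total - SS_wg
  SS_AP <- SS_wg - SS_WP
  df <- c(AG = G - 1, AP = P - G, WP = N - P)
  sumnp2_g <- vapply(gidx, function(ix) sum(n_p[ix]^2), 0)
  n1 <- (N - sum(sumnp2_g / n_g)) / max(df[["AP"]], 1)
  n2 <- (sum(sumnp2_g / n_g) - sum(n_p^2) / N) / max(df[["AG"]], 1)
  n3 <- (N - sum(n_g^2) / N) / max(df[["AG"]], 1)
  MS <- unname(c(if (df["AG"] > 0) SS_AG / df["AG"] else NA_real_,
                 if (df["AP"] > 0) SS_AP / df["AP"] else NA_real_,
                 if (df["WP"] > 0) SS_WP / df["WP"] else NA_real_))
  s_c <- MS[3]
  ## P == G: the among-populations-within-groups level does not exist
  s_b <- if (df[["AP"]] == 0) 0 else unname((MS[2] - s_c) / n1)
  s_a <- if (is.na(MS[1])) NA_real_ else unname((MS[1] - s_c - n2 * s_b) / n3)
  if (G == 1L) {
    ## collapsed group level: classical two-level AMOVA among populations
    tot <- s_b + s_c
    return(list(SS = c(AG = 0, AP = unname(SS_AP), WP = unname(SS_WP),
                       total = SS_total),
                df = df, sigma2 = c(a = NA_real_, b = s_b, c = s_c),
                Phi_CT = NA_real_,
                Phi_SC = if (isTRUE(tot != 0)) s_b / tot else NA_real_,
                Phi_ST = if (isTRUE(tot != 0)) s_b / tot else NA_real_))
  }
  tot <- s_a + s_b + s_c
  list(SS = c(AG = unname(SS_AG), AP = unname(SS_AP), WP = unname(SS_WP),
              total = SS_total),
       df = df, sigma2 = c(a = s_a, b = s_b, c = s_c),
       Phi_CT = if (isTRUE(tot != 0)) s_a / tot else NA_real_,
       Phi_SC = if (isTRUE(s_b + s_c != 0)) s_b / (s_b + s_c) else NA_real_,
       Phi_ST = if (isTRUE(tot != 0)) (s_a + s_b) / tot else NA_real_)
}

.amova_prepare <- function(d, populations, groups) {
  d2 <- unclass(d)
  attributes(d2)[c("sites_used", "missing_policy")] <- NULL
  storage.mode(d2) <- "double"
  stopifnot(nrow(d2) == length(populations),
            length(populations) == length(groups))
  pop_lab <- unique(populations)
  pop <- match(populations, pop_lab)
  if (any(vapply(pop_lab, function(p)
    length(unique(groups[populations == p])), 1L) != 1L))
    stop("every population must map to exactly one group")
  gop_lab <- vapply(pop_lab, function(p)
    unique(groups[populations == p]), groups[1])
  gop <- match(gop_lab, unique(gop_lab))
  list(d2 = d2, pop = pop, gop = gop, pop_lab = pop_lab,
       grp_lab = unique(gop_lab))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA on a pairwise-difference matrix: among groups
#' (species), among populations within groups, and within populations.
#' Sums of squares follow the Excoffier-Smouse-Quattro decomposition with
#' unbalanced-design coefficients; the number of pairwise differences is
#' used directly as the squared inter-haplotype distance, as in ARLEQUIN.
#' Negative variance components are reported as computed (not clamped),
#' with a warning; percent variation is computed on the raw components.
#'
#' @param d A `pdiff_matrix` (or plain symmetric matrix of squared
#'   distances) with one row per sample.
#' @param populations Population label per sample (row order of `d`).
#' @param groups Group (species) label per sample; must be constant within
#'   each population. A single group collapses the design to the classical
#'   two-level AMOVA (Phi_ST among populations; Phi_CT undefined).
#' @param n_perm If positive, permutation p-values are attached via
#'   [amova_significance()].
#' @param seed Seed for the permutations.
#' @return Object of class `amova_result`: list with `df`, `SS`, `sigma2`
#'   (variance components a/b/c), `percent_variation`, `Phi_CT`, `Phi_SC`,
#'   `Phi_ST`, and (when requested) `p_values` and `n_perm`. Some field
#'   tables label the within-population index "F_IS"; for
#'   haplotype-distance AMOVA the corresponding total index is Phi_ST =
#'   (a+b)/total, reported here under its standard name.
#' @export
amova <- function(d, populations, groups, n_perm = 0, seed = NULL) {
  prep <- .amova_prepare(d, populations, groups)
  core <- .amova_core(prep$d2, prep$pop, prep$gop)
  if (any(is.finite(core$sigma2) & core$sigma2 < 0))
    warning("negative variance component(s) reported as computed")
  pct <- 100 * core$sigma2 / sum(core$sigma2, na.rm = TRUE)
  res <- structure(c(core, list(percent_variation = pct,
                                degenerate = any(is.na(core$sigma2)))),
                   class = "amova_result")
  if (n_perm > 0) {
    res$p_values <- amova_significance(d, populations, groups,
                                       n_perm = n_perm, seed = seed)
    res$n_perm <- n_perm
  }
  res
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = as.integer(x$df),
    SS = round(x$SS[1:3], 4),
    sigma2 = round(x$sigma2, 4),
    pct = round(x$percent_variation, 2))
  if (!is.null(x$p_values))
    tab$P <- round(x$p_values[c("Phi_CT", "Phi_SC", "Phi_ST")], 4)
  print(tab, row.names = FALSE)
  cat("Phi_CT =", format(x$Phi_CT, digits = 4),
      " Phi_SC =", format(x$Phi_SC, digits = 4),
      " Phi_ST =", format(x$Phi_ST, digits = 4), "\n")
  invisible(x)
}

#' Stratified permutation significance for AMOVA fixation indices
#'
#' Permutation schemes: `Phi_CT` permutes whole populations among groups;
#' `Phi_SC` permutes samples among populations within their group;
#' `Phi_ST` permutes samples among all populations. Each p-value uses the
#' `+1` correction: `p = (count >= observed + 1) / (n_perm + 1)`.
#'
#' @inheritParams amova
#' @param n_perm Number of permutations (>= 100 recommended).
#' @return Named vector of p-values for `Phi_CT`, `Phi_SC`, `Phi_ST`.
#' @export
amova_significance <- function(d, populations, groups, n_perm = 999,
                               seed = NULL) {
  prep <- .amova_prepare(d, populations, groups)
  obs <- .amova_core(prep$d2, prep$pop, prep$gop)
  P <- length(prep$gop)
  with_seed(seed, {
    ge_ct <- ge_sc <- ge_st <- 0L
    has_ct <- !is.na(obs$Phi_CT)
    for (b in seq_len(n_perm)) {
      if (has_ct) {
        perm_gop <- sample(prep$gop)
        r <- .amova_core(prep$d2, prep$pop, perm_gop)
        if (!is.na(r$Phi_CT) && r$Phi_CT >= obs$Phi_CT) ge_ct <- ge_ct + 1L
      }

      perm_pop <- prep$pop
      for (g in unique(prep$gop)) {
        members <- which(prep$gop[prep$pop] == g)
        perm_pop[members] <- sample(prep$pop[members])
      }
      r <- .amova_core(prep$d2, perm_pop, prep$gop)
      if (!is.na(r$Phi_SC) && r$Phi_SC >= obs$Phi_SC) ge_sc <- ge_sc + 1L

      perm_pop <- sample(prep$pop)
      r <- .amova_core(prep$d2, perm_pop, prep$gop)
      if (!is.na(r$Phi_ST) && r$Phi_ST >= obs$Phi_ST) ge_st <- ge_st + 1L
    }
    c(Phi_CT = if (has_ct) (ge_ct + 1) / (n_perm + 1) else NA_real_,
      Phi_SC = (ge_sc + 1) / (n_perm + 1),
      Phi_ST = (ge_st + 1) / (n_perm + 1))
  })
}
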