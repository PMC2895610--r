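#' Observed mismatch distribution
#'
#' Frequency spectrum of pairwise difference counts over all unordered
#' pairs of sequences in scope. Unimodal, roughly Poisson-shaped spectra
#' are the signature of a sudden demographic expansion.
#'
#' @param d A `pdiff_matrix` from [pairwise_differences()].
#' @param ids Optional subset of sequence labels defining the scope (e.g.
#'   one species); default all.
#' @return Object of class `mismatch_distribution`: list with `freq`
#'   (relative frequencies over difference classes `0..j_max`) and
#'   `n_pairs`.
#' @export
observed_mismatch <- function(d, ids = NULL) {
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(d))
    if (length(miss)) stop("unknown labels: ", paste(miss, collapse = ", "))
    d <- d[ids, ids, drop = FALSE]
  }
  if (nrow(d) < 2L) stop("need at least 2 sequences in scope")
  v <- d[upper.tri(d)]
  freq <- tabulate(v + 1L, max(v) + 1L) / length(v)
  structure(list(freq = freq, n_pairs = length(v)),
            class = "mismatch_distribution")
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' In the limit of an infinitely large post-expansion population the
#' expected frequency of pairs differing at `j` sites is the convolution of
#' a Poisson(`tau`) count of post-expansion mutations with the geometric
#' equilibrium spectrum of the pre-expansion population:
#' `F_j = sum_{i=0}^{j} e^{-tau} tau^i / i! * theta0^{j-i} /
#' (theta0 + 1)^{j-i+1}`, renormalized over `0..j_max`.
#'
#' @param theta0 Pre-expansion scaled diversity (per sequence).
#' @param tau Scaled expansion age (mutational units).
#' @param j_max Largest difference class; a warning is raised when the
#'   untruncated classes `0..j_max` hold less than 99.9% of the mass.
#' @param renormalize Renormalize over `0..j_max` (default `TRUE`).
#' @return A `mismatch_distribution` (with `n_pairs = NA`).
#' @export
expected_mismatch <- function(theta0, tau, j_max, renormalize = TRUE) {
  stopifnot(theta0 >= 0, tau >= 0, j_max >= 0)
  f <- .expected_freq(theta0, tau, j_max, renormalize = FALSE)
  if (sum(f) < 0.999)
    warning("truncation: classes 0..", j_max, " hold only ",
            format(sum(f), digits = 4), " of the expected mass")
  if (renormalize) f <- f / sum(f)
  structure(list(freq = f, n_pairs = NA_integer_),
            class = "mismatch_distribution")
}

## Poisson(tau) (*) Geometric(theta0) convolution over 0..j_max; short
## explicit convolution (j_max is small) without warning machinery, for
## use inside optimizer loops
.expected_freq <- function(theta0, tau, j_max, renormalize = TRUE) {
  pois <- stats::dpois(0:j_max, tau)
  geo <- theta0^(0:j_max) / (theta0 + 1)^(1:(j_max + 1))
  f <- numeric(j_max + 1)
  for (i in 0:j_max) {
    jr <- i:j_max
    f[jr + 1] <- f[jr + 1] + pois[i + 1] * geo[jr - i + 1]
  }
  if (renormalize) f / sum(f) else f
}

## pad two frequency vectors with zero classes to a common support
.ssd <- function(f1, f2) {
  k <- max(length(f1), length(f2))
  sum((c(f1, rep(0, k - length(f1))) - c(f2, rep(0, k - length(f2))))^2)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Least-squares fit of `(theta0, tau)` (with `theta1` fixed at infinity)
#' minimizing the sum of squared deviations between observed and expected
#' class frequencies over the observed support, by Nelder-Mead on a
#' square-root scale (which enforces the non-negativity bounds) from a
#' moment start (`tau` at the observed mean difference count).
#'
#' @param obs A `mismatch_distribution` from [observed_mismatch()].
#' @return Object of class `expansion_fit`: list with `theta0`, `theta1`
#'   (`Inf`), `tau`, `SSD`, `j_max`, `obs`, `expected` (fitted frequencies),
#'   `n_pairs` and `converged`.
#' @export
fit_expansion <- function(obs) {
  freq <- obs$freq
  j_max <- length(freq) - 1L
  mean_d <- sum((0:j_max) * freq)
  if (mean_d == 0) {               # all sequences identical
    return(structure(list(theta0 = 0, theta1 = Inf, tau = 0, SSD = 0,
                          j_max = j_max, obs = freq, expected = 1,
                          n_pairs = obs$n_pairs, converged = TRUE),
                     class = "expansion_fit"))
  }
  objective <- function(p)
    sum((freq - .expected_freq(p[1]^2, p[2]^2, j_max))^2)
  starts <- list(c(sqrt(0.1), sqrt(mean_d)),
                 c(sqrt(max(mean_d / 2, 0.05)), sqrt(mean_d / 2)),
                 c(sqrt(mean_d), 0.1))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, objective, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta0 <- best$par[1]^2
  tau <- best$par[2]^2
  structure(list(theta0 = theta0, theta1 = Inf, tau = tau,
                 SSD = best$value, j_max = j_max, obs = freq,
                 expected = .expected_freq(theta0, tau, j_max),
                 n_pairs = obs$n_pairs,
                 converged = best$convergence == 0),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat("sudden-expansion fit: tau =", format(x$tau, digits = 4),
      " theta0 =", format(x$theta0, digits = 4),
      " theta1 = Inf\n  SSD =", format(x$SSD, digits = 4))
  if (!is.null(x$p_SSD)) cat("  p(SSD) =", format(x$p_SSD, digits = 3))
  if (!is.null(x$tau_CI))
    cat("  tau 95% CI [", format(x$tau_CI[1], digits = 3), ",",
        format(x$tau_CI[2], digits = 3), "]")
  cat("\n")
  invisible(x)
}

#' Parametric-bootstrap goodness-of-fit test of the expansion model
#'
#' Simulates `B` coalescent samples of size `n` under the fitted expansion
#' history (pre-expansion diversity `theta0`, infinite post-expansion size,
#' expansion age `tau`, ideal infinite-sites mutation), refits the model to
#' each replicate, and reports the fraction of replicate SSDs at least as
#' large as the observed SSD. Refitting each replicate mirrors the
#' conservative ARLEQUIN procedure.
#'
#' @param fit An `expansion_fit`.
#' @param n Sample size the observed distribution came from.
#' @param B Bootstrap replicates.
#' @param seed Optional integer seed.
#' @return Object of class `ssd_test`: list with `p_SSD`, `SSD_obs` and
#'   per-replicate vectors `ssd`, `tau`, `theta0` (the `tau` vector feeds
#'   [tau_ci()]).
#' @export
ssd_test <- function(fit, n, B = 1000, seed = NULL) {
  stopifnot(n >= 2, B >= 1)
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      v <- .sim_pair_diffs(fit$theta0, Inf, fit$tau, n)
      freq <- tabulate(v + 1L, max(v) + 1L) / length(v)
      f <- fit_expansion(structure(list(freq = freq, n_pairs = length(v)),
                                   class = "mismatch_distribution"))
      c(f$SSD, f$tau, f$theta0)
    })
  })
  m <- do.call(rbind, reps)
  structure(list(p_SSD = mean(m[, 1] >= fit$SSD), SSD_obs = fit$SSD,
                 ssd = m[, 1], tau = m[, 2], theta0 = m[, 3], B = B),
            class = "ssd_test")
}

#' Percentile confidence interval for the expansion age
#'
#' Linear-interpolation empirical quantiles (type 7) of the bootstrap
#' replicate `tau` estimates.
#'
#' @param tau_values Numeric vector of bootstrap `tau` estimates (100 or
#'   more recommended).
#' @param level Coverage in percent (default 95).
#' @return Length-2 vector `(lower, upper)`.
#' @export
tau_ci <- function(tau_values, level = 95) {
  stopifnot(length(tau_values) >= 2, level > 0, level < 100)
  a <- (1 - level / 100) / 2
  unname(stats::quantile(tau_values, c(a, 1 - a), type = 7))
}

#' Convert an expansion age to calendar years
#'
#' `t = tau / (2u)` generations, with `u = mu_site_per_gen * L` the
#' mutation rate per sequence per generation, divided by the number of
#' generations per year.
#'
#' @param tau Scaled expansion age.
#' @param mu_site_per_gen Mutation rate per site per generation.
#' @param L Sequence length in bp.
#' @param gens_per_year Generations per year.
#' @return Expansion time in years.
#' @export
expansion_time <- function(tau, mu_site_per_gen, L, gens_per_year) {
  stopifnot(tau >= 0, mu_site_per_gen > 0, L >= 1, gens_per_year > 0)
  tau / (2 * mu_site_per_gen * L) / gens_per_year
}
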