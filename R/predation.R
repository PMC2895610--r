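#' Proportion of prey missing, with variance-stabilizing transform
#'
#' Prey mortality is equated with the proportion of prey missing,
#' `p = (P_I - P_T) / P_I`, and arcsine-square-root transformed
#' (`asin(sqrt(p))`, radians) for analysis.
#'
#' @param P_I Initial prey count (> 0).
#' @param P_T Final prey count, `0 <= P_T <= P_I`. Vectorized.
#' @return List with `proportion` and `transformed`.
#' @export
proportion_missing <- function(P_I, P_T) {
  stopifnot(all(P_I > 0), all(P_T >= 0), all(P_T <= P_I))
  p <- (P_I - P_T) / P_I
  list(proportion = p, transformed = asin(sqrt(p)))
}

#' Predation rate coefficient K
#'
#' Exponential prey-decay rate per predator per hour implied by the
#' Lotka-Volterra predation term `dP/dt = -K X P`:
#' `K = ln(P_I / P_T) / (X T)`. Defined only in predator treatments
#' (`X >= 1`) and only when at least one prey survives; its ratio form
#' makes it identical whether counts are per experimental unit or per
#' liter.
#'
#' @param P_I Initial prey count.
#' @param P_T Final prey count (>= 1; `K` is undefined at total
#'   extirpation and no continuity correction is applied).
#' @param X Predators per experimental unit (>= 1).
#' @param T_hours Trial duration in hours (> 0). Vectorized.
#' @return Numeric `K` (per predator per hour).
#' @export
predation_rate_K <- function(P_I, P_T, X, T_hours) {
  stopifnot(all(P_I > 0), all(T_hours > 0))
  if (any(X < 1))
    stop("K is defined in predator treatments only (X >= 1)")
  if (any(P_T < 1))
    stop("K undefined when no prey survive (P_T = 0)")
  log(P_I / P_T) / (X * T_hours)
}

#' Per-cell summaries of predation trials
#'
#' Mean and standard error of the proportion of prey missing (raw and
#' arcsine-square-root transformed) per species-by-treatment cell, and of
#' the predation rate coefficient `K` in predator cells. Trials with zero
#' survivors are excluded from the `K` summary (where `K` is undefined)
#' and counted in `n_K_undefined`.
#'
#' @param trials Data frame with columns `prey_species`, `treatment`,
#'   `P_I`, `P_T`, `X`, `T_hours` (e.g. from
#'   [simulate_predation_trials()]).
#' @return Object of class `predation_summary`: a data frame with one row
#'   per cell (`prey_species`, `treatment`, `n`, `mean_proportion`,
#'   `se_proportion`, `mean_transformed`, `se_transformed`, `mean_K`,
#'   `se_K`, `n_K_undefined`).
#' @export
summarize_cells <- function(trials) {
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                    else NA_real_
  cells <- unique(trials[, c("prey_species", "treatment")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- trials[trials$prey_species == cells$prey_species[i] &
                trials$treatment == cells$treatment[i], , drop = FALSE]
    pm <- proportion_missing(r$P_I, r$P_T)
    predator <- all(r$X >= 1)
    ok <- r$P_T >= 1
    K <- if (predator && any(ok))
      predation_rate_K(r$P_I[ok], r$P_T[ok], r$X[ok], r$T_hours[ok])
    else NULL
    data.frame(prey_species = cells$prey_species[i],
               treatment = cells$treatment[i], n = nrow(r),
               mean_proportion = mean(pm$proportion),
               se_proportion = se(pm$proportion),
               mean_transformed = mean(pm$transformed),
               se_transformed = se(pm$transformed),
               mean_K = if (is.null(K)) NA_real_ else mean(K),
               se_K = if (is.null(K)) NA_real_ else se(K),
               n_K_undefined = if (predator) sum(!ok) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("predation_summary", "data.frame")
  out
}
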