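#' Mean and net between-species divergence per site
#'
#' `d_xy` is the mean per-site difference over all between-species pairs;
#' `d_a = d_xy - (d_x + d_y)/2` subtracts the average within-species
#' diversity, giving the moment estimator of divergence accumulated since
#' isolation. Used here as a desk-scale stand-in for full
#' isolation-with-migration machinery: migration (or large ancestral
#' diversity differences) biases it, so scenarios declaring migration
#' attach a warning downstream.
#'
#' @param d A `pdiff_matrix` from [pairwise_differences()] (complete
#'   deletion recommended so all pairs share one site scale).
#' @param species Species label per sample (row order of `d`); exactly two
#'   species, each with >= 2 sequences.
#' @param L Number of sites to divide by; defaults to the matrix's
#'   `sites_used` when scalar.
#' @return List with `d_xy`, `d_x`, `d_y`, `d_a` (all per site) and `L`.
#' @export
net_divergence <- function(d, species, L = NULL) {
  stopifnot(nrow(d) == length(species))
  sp <- unique(species)
  if (length(sp) != 2L) stop("need exactly two species")
  if (is.null(L)) {
    L <- attr(d, "sites_used")
    if (is.null(L) || length(L) != 1L)
      stop("L must be given when sites_used is not a scalar")
  }
  a <- which(species == sp[1]); b <- which(species == sp[2])
  if (length(a) < 2L || length(b) < 2L)
    stop("each species needs at least 2 sequences")
  dm <- unclass(d)
  d_xy <- mean(dm[a, b]) / L
  d_x <- mean(dm[a, a][upper.tri(diag(length(a)))]) / L
  d_y <- mean(dm[b, b][upper.tri(diag(length(b)))]) / L
  list(d_xy = d_xy, d_x = d_x, d_y = d_y,
       d_a = d_xy - (d_x + d_y) / 2, L = L, species = sp)
}

#' Divergence time from net divergence
#'
#' `t = d_a / (2 mu)` years, with `mu` the per-site per-year substitution
#' rate. Negative net divergence (within-species diversity exceeding
#' between-species divergence) yields an undefined time, returned as `NA`
#' with a flag.
#'
#' @param d_a Net per-site divergence (e.g. from [net_divergence()]).
#' @param mu_site_per_year Substitution rate per site per year (> 0).
#' @return List with `t_years`, `defined`, `d_a` and `mu_site_per_year`.
#' @export
divergence_years <- function(d_a, mu_site_per_year) {
  stopifnot(mu_site_per_year > 0)
  if (d_a < 0)
    return(list(t_years = NA_real_, defined = FALSE, d_a = d_a,
                mu_site_per_year = mu_site_per_year))
  list(t_years = d_a / (2 * mu_site_per_year), defined = TRUE, d_a = d_a,
       mu_site_per_year = mu_site_per_year)
}
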