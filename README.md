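# idpopgen

Population-genetic and ecological statistics for detecting and dating
**intermediate genetic divergence** — the stages between panmixia and
reciprocal monophyly — in recently separated species pairs, motivated by
lacustrine cyclic parthenogens (*Daphnia*) sampled from many lake
populations at one mitochondrial and several nuclear markers.

For a pair of putative sister species the package asks, from multilocus
alignments with two allele copies per individual:

* How far has each species proceeded towards exclusive ancestry on each
  gene genealogy? — the **genealogical sorting index**
  `gsi = (gs − gs_min)/(1 − gs_min) ∈ [0, 1]`, with
  `gs = (k−1)/Σ_u(d_u − 2)` summed over the nodes uniting the group
  through its MRCA; 1 means monophyly, permutation tests give
  significance, and balanced subsampling removes the power loss from
  unequal species sampling.
* How is molecular variance partitioned? — three-level **AMOVA**
  (between species Φ_CT, among populations within species Φ_SC, total
  Φ_ST) from pairwise-difference matrices, with stratified permutation
  p-values.
* Did the lineages expand after deglaciation, and when? — **mismatch
  distributions** fit to the sudden-expansion model
  `F_j = Σ_i e^(−τ) τ^i/i! · θ0^(j−i)/(θ0+1)^(j−i+1)`, SSD goodness of
  fit by parametric bootstrap, percentile CIs for τ, and the dating
  `t = τ/(2u)` generations with `u` the per-sequence per-generation
  mutation rate.
* When did the species split? — the moment clock `t = d_a/(2μ)` on the
  net divergence `d_a = d_xy − (d_x + d_y)/2`, a desk-scale substitute
  for full isolation-with-migration machinery, validated by simulation
  recovery.
* How do haplotypes relate? — **median-joining networks** with inferred
  median (ancestral) vectors and mutation-step edge weights.
* Do the species differ in predator vulnerability? — the predation rate
  coefficient `K = ln(P_I/P_T)/(X·T)` and the arcsine-square-root
  proportion-missing transform for laboratory predation trials.

A two-population structured-coalescent generator (divergence, optional
migration, stepwise expansion, infinite-sites mutation) plus a binomial
predation-trial generator produce synthetic data with exactly the
structure the analyses assume; every estimator is tested against
independent brute-force oracles and simulation recovery. See the methods
vignette (`vignettes/intermediate-divergence.Rmd`) for models,
conventions and limitations.

## Worked example

```r
library(idpopgen)

## date a demographic expansion from a published tau estimate:
## tau = 4.765, u = 6.6e-8 /site/generation over 631 bp, 5 gen/year
expansion_time(tau = 4.765, mu_site_per_gen = 6.6e-8, L = 631,
               gens_per_year = 5)
#> [1] 11441.68           # years before present

## simulate an expanded population and recover the expansion
sc  <- coalescent_scenario(theta0 = 1, theta1 = 1000,
                           tau_expansion = 4.765, L = 1500)
sim <- simulate_expansion_population(sc, n = 50, seed = 1)
fit <- fit_expansion(observed_mismatch(pairwise_differences(sim$aln)))
st  <- ssd_test(fit, n = 50, B = 500, seed = 2)
fit$p_SSD <- st$p_SSD; fit$tau_CI <- tau_ci(st$tau)
fit
#> sudden-expansion fit: tau = 4.832  theta0 = 1.696  theta1 = Inf
#>   SSD = 0.005115  p(SSD) = 0.104  tau 95% CI [ 2.97 , 7.62 ]
```

The fitted τ ≈ 4.8 recovers the simulated 4.765; the SSD p-value of 0.10
means the observed spectrum is compatible with the expansion model, and
the CI is the 95th-percentile interval of 500 refitted bootstrap
replicates.

```r
## two-species divergence: sorting index and moment clock
sim2 <- simulate_two_population(coalescent_scenario(), seed = 3)
gsi_test(sim2$genealogy,
         grep("^A", sim2$genealogy$tip.label, value = TRUE),
         n_perm = 999, seed = 4)
#> gsi = 1 (gs = 1 )  p = 0.001

nd <- net_divergence(pairwise_differences(sim2$aln), sim2$aln$meta$species)
divergence_years(nd$d_a, 3.3e-6)$t_years
#> [1] 16045.9            # single-locus draw around the simulated 20,600

predation_rate_K(P_I = 20, P_T = 10, X = 1, T_hours = 24)
#> [1] 0.02888113         # per predator per hour
```

## Analysis workflow

Numbered drivers under `analysis/` run the full pipeline on synthetic
data and write tables under `results/`:

1. `01_simulate_data.R` — four-marker, two-species dataset (FASTA +
   metadata TSV + true genealogies + scenario JSON)
2. `02_haplotype_networks.R` — median-joining networks (GraphML/TSV)
3. `03_gsi.R` — gsi per marker with permutation tests and balanced
   subsampling
4. `04_mismatch_expansion.R` — mismatch fits, SSD tests, τ CIs, dating,
   Tajima's D, four-gamete test
5. `05_amova.R` — per-marker and concatenated AMOVA tables
6. `06_divergence_time.R` — net divergence and divergence times
7. `07_predation.R` — predation-trial summaries and K

```sh
Rscript analysis/01_simulate_data.R --seed 7 && Rscript analysis/03_gsi.R
```

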