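---
title: "Quantifying intermediate divergence between cyclic parthenogens"
author: "idpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intermediate divergence between cyclic parthenogens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpopgen)
```

## The problem

Recently separated species pairs — here, lacustrine *Daphnia* that
reproduce mostly clonally with episodic sex — occupy the middle of the
lineage-divergence continuum: gene frequencies have diverged, younger
haplotypes are private to one species, yet neither species is
reciprocally monophyletic on any single gene genealogy. `idpopgen`
implements the statistics used to detect and date this *intermediate
divergence* from multilocus sequence samples spread over many lake
populations, together with a coalescent generator that produces data with
exactly the structure those statistics assume:

* labelled alignments with the diploid two-allele-copy convention
  (`labeled_alignment`, `duplicate_haploid_copies`),
* median-joining haplotype networks (`median_joining`),
* the genealogical sorting index with permutation tests and balanced
  subsampling (`gsi`, `gsi_test`, `gsi_balanced`),
* mismatch distributions under the sudden-expansion model with SSD
  goodness of fit and expansion dating (`fit_expansion`, `ssd_test`,
  `expansion_time`),
* three-level AMOVA with stratified permutation significance (`amova`),
* a moment-based divergence-time estimator (`net_divergence`,
  `divergence_years`), and
* the predation rate coefficient for the companion laboratory
  experiments (`predation_rate_K`).

## Data model and conventions

A `labeled_alignment` couples equal-length nucleotide sequences over
`A,C,G,T,-,N` with per-sample metadata (`individual_id`, `species`,
`population`, `marker`, `allele_copy`). Nuclear markers carry two phased
allele copies per individual (`a`/`b`); a haploid mitochondrial marker is
replicated twice per individual so every individual contributes the same
number of gene copies at every marker. IUPAC ambiguity codes other than
`N` are recoded to `N`: phased (cloned) data carry no ambiguity codes, so
any leftover code is best treated as missing. Alignment columns are
0-based internally and 1-based in every report.

Two missing-data policies are exposed because the analysis convention of
record does not state one: `complete_deletion` (default for mismatch and
network stages — one shared site scale for all pairs) and
`pairwise_deletion` (available for AMOVA). Distances are Hamming counts
over the retained sites.

## The coalescent generator

`coalescent_scenario()` collects the demographic parameters; its defaults
are the mitochondrial study conditions: 20 gene copies per species,
divergence 20,600 years ago, no migration, a sudden expansion of
mutational age $\tau = 4.765$, sequence length 631 bp, five generations
per year, and the mitochondrial substitution rate pair
($3.3\times10^{-6}$ /site/year; $6.6\times10^{-7}$ /site/generation at
five generations per year).

Three simulators share one structured-coalescent engine with
piecewise-constant deme sizes and exponential waiting times:

* `simulate_single_population(theta, n, L)` — stationary Kingman
  coalescent in mutational time (branch lengths are expected mutations
  per sequence; a deme of scaled diversity $\theta$ has pairwise
  coalescence rate $2/\theta$, so $E(\pi) = \theta$ and
  $E(S) = a_1\theta$).
* `simulate_expansion_population(scenario, n)` — stepwise size change at
  scaled time $\tau/2$: diversity $\theta_1$ (possibly $\infty$) after
  the expansion, $\theta_0$ before it.
* `simulate_two_population(scenario)` — two demes exchanging `mig_rate`
  migrants per generation merge into one ancestral deme at
  `t_div_years * gens_per_year` generations; time is kept in generations
  internally and converted to years only at the interface, because the
  source rates mix per-year and per-generation units.

Mutations follow the infinite-sites model: Poisson numbers per branch,
placed on distinct sites drawn without replacement from the `L`
positions, each site derived once (so the four-gamete test is empty by
construction — the analyses assume no recombination). Requesting more
mutations than sites raises a site-exhaustion error advising a larger
`L` rather than silently recycling sites. All simulators are pure
functions of (parameters, seed).

Two deliberate unit decisions deserve emphasis. First, the source
tradition reports the mitochondrial rate as $3.3\times10^{-6}$/site/year
in one analysis and $6.6\times10^{-8}$/site/generation (i.e.
$3.3\times10^{-7}$/year at 5 generations/year) in another — a tenfold
discrepancy. The scenario therefore carries *both* rates explicitly
(`mu_site_per_year` for divergence dating, `mu_site_per_gen` for mutation
placement and expansion dating) and never reconciles them; the default
`mu_site_per_gen` is the per-year rate divided by `gens_per_year` so that
the generation-time simulation is internally consistent with the
per-year divergence arithmetic. Second, the expansion age $\tau$ is a
*mitochondrial* estimate in mitochondrial mutational units; when the
analysis scripts simulate nuclear markers they anchor the same expansion
in years and convert it into each marker's own mutational units
($\tau_m = 2 u_m t$), since applying the mitochondrial $\tau$ verbatim to
nuclear rates would date the expansion older than the species split.

What the generator does *not* emulate: recombination, selection,
ascertainment bias, sequencing error, within-species population
structure (population labels partition a panmictic species sample —
useful for permutation calibration, but the among-population AMOVA
component is genuinely near zero in simulated data), and
isolation-with-migration posterior sampling. Tests that pass on this
generator therefore validate the estimators under their own model
assumptions, not robustness to these real-data features.

## Mismatch distributions and expansion dating

The observed mismatch distribution is the frequency spectrum of pairwise
difference counts (`observed_mismatch`). Under a sudden expansion with
infinite post-expansion size the expected class frequencies are a
Poisson($\tau$) count of post-expansion mutations convolved with the
geometric equilibrium spectrum of the pre-expansion population:

$$F_j \;=\; \sum_{i=0}^{j} e^{-\tau}\frac{\tau^i}{i!}\cdot
\frac{\theta_0^{\,j-i}}{(\theta_0+1)^{\,j-i+1}},$$

renormalized over the evaluated classes $0..j_{\max}$ (the untruncated
mean is $\tau + \theta_0$, which the tests verify numerically).
`fit_expansion` minimizes the sum of squared deviations between observed
and expected frequencies over the observed support by Nelder–Mead on a
square-root parameter scale (a smooth way to impose
$\theta_0, \tau \ge 0$), from three starts including the moment start
$\tau \approx$ mean difference count; $\theta_1$ is fixed at $\infty$ in
the default model, matching standard practice, with the finite-$\theta_1$
expectation available as an extension point. All-identical input returns
the degenerate fit $(\hat\theta_0, \hat\tau) = (0, 0)$ without invoking
the optimizer.

Goodness of fit (`ssd_test`) is a parametric bootstrap: simulate `B`
coalescent samples of size `n` under the fitted history (ideal infinite
sites), refit each replicate, and report the fraction of replicate SSDs
at least as large as the observed SSD. The reported "permutation
replicates" of the original analyses are interpreted this way — there are
no labels to permute in a one-sample goodness-of-fit problem — and each
replicate is *refitted*, the conservative choice. The p-value is the
plain fraction (a perfect fit gives $p = 1$ exactly). The 95th-percentile
interval for $\tau$ (`tau_ci`) uses linear-interpolation empirical
quantiles (R type 7) of the replicate $\hat\tau$ values. Desk-scale
defaults use `B = 1000` (tests use 200); the original scale of
10,000 replicates is reachable by argument.

The fitted $\hat\tau$ carries the well-known upward tendency of
least-squares mismatch estimation on single-genealogy data (the realized
spectrum of one tree is tighter than the inter-tree expectation, so the
fit shifts mass from $\theta_0$ to $\tau$); the bootstrap CI inherits the
same mechanism, and the simulation suite measures both the recovery band
of the median $\hat\tau$ and the CI's empirical coverage rather than
assuming unbiasedness.

Expansion age converts to calendar years by
$t = \tau/(2u)$ generations with $u$ the *per-sequence per-generation*
rate (`expansion_time(tau, mu_site_per_gen, L, gens_per_year)`). The
sequence length is an explicit argument and is never hard-coded: the
reference worked examples print times that back-solve to an effective
length of about 633 sites against a stated 631 bp fragment, so the
package reproduces those times to within 0.5% at `L = 631` and exactly at
the effective length.

`tajimas_d` (standard 1989 statistic, undefined-flagged at $S = 0$) and
`four_gamete_test` (all four haplotype combinations at a pair of
biallelic sites; non-biallelic segregating sites skipped and reported)
check the neutrality and no-recombination assumptions behind the
demographic inference.

## AMOVA

`amova` decomposes molecular variance among groups (species), among
populations within groups, and within populations, from squared
inter-haplotype distances — for sequence data the pairwise difference
count *is* the squared Euclidean distance, so the distance matrix enters
the sums of squares directly. Variance components come from equating
mean squares to their expectations with the standard unbalanced-design
coefficients; the fixation indices are
$\Phi_{CT} = \sigma^2_a/\sigma^2_T$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$,
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T$. Negative components
are reported as computed (with a warning), not clamped, and percent
variation uses the raw components — honest table output at the cost of
occasional percentages outside $[0, 100]$. The field tradition sometimes
labels the within-population index "F_IS"; haplotype-distance AMOVA
yields $\Phi_{ST}$ for that slot and the output uses the standard name.
A single-group design collapses to the classical two-level
$\Phi_{ST}$.

`amova_significance` uses stratified permutation schemes — whole
populations among groups for $\Phi_{CT}$, samples among populations
within groups for $\Phi_{SC}$, samples among all populations for
$\Phi_{ST}$ — with the $+1$ correction
$p = (\#\{\ge \text{obs}\}+1)/(n_{perm}+1)$. Note that the size of the
$\Phi_{CT}$ test is limited by the number of distinct whole-population
reassignments: with two populations per group the space is trivial and
no small p-value is attainable, which is why the calibration experiments
use 16 populations. Multi-marker analyses concatenate sequences by
default (matching a combined-alignment convention); per-locus runs are
available by calling per marker.

## Genealogical sorting index

For a group of $k$ tips on a rooted tree (polytomies allowed), the raw
statistic is $gs = n/\sum_{u}(d_u - 2)$, where the sum runs over the
internal nodes on the paths from the group's tips through their most
recent common ancestor, $d_u$ is the node degree (children plus one for
the parent; the root has no parent), and $n = k-1$ is the minimum number
of nodes needed to unite the group. For any monophyletic group the sum
telescopes to $k-1$, so $gs = 1$ on arbitrary multifurcating trees. The
normalized index rescales between the dispersed floor
$gs_{\min} = (k-1)/(T-2)$ (the sum over *all* internal nodes of a
$T$-tip tree) and the monophyly ceiling of 1:
$gsi = (gs - gs_{\min})/(1 - gs_{\min})$, clamped to $[0,1]$. Two
boundary conventions are fixed deliberately: a group comprising all tips,
and a singleton group, are trivially exclusive and return 1; on a
three-tip tree the normalization is degenerate ($gs_{\min} = 1$) and 1 is
returned. The statistic is topological — branch lengths are ignored —
and the implementation is pinned against an independent path-based
transcription in the test suite rather than trusted from a single
formula reading. One consequence of the floor-based normalization is
worth knowing: pruning a tip outside the group can only improve (or
leave unchanged) the raw $gs$, but may *lower* the normalized $gsi$,
because the floor $(k-1)/(T-2)$ rises as the tree shrinks — so gsi
values are comparable across groups on one tree, not across trees of
different sizes.

`gsi_test` permutes the group assignment uniformly over tips ($+1$
correction); `gsi_balanced` repeatedly prunes whole individuals (both
allele copies together) from the over-represented group until group
sizes match, recomputing gsi on each pruned tree — unbalanced group
representation lowers the power of exclusivity tests, so the balanced
median is the headline number. `neighbor_joining` (with midpoint or
outgroup rooting) is included as plumbing so the pipeline can build a
usable rooted topology from its own distance matrices; it is not a
substitute for likelihood tree inference.

## Median-joining networks

`minimum_spanning_network` keeps every edge that occurs in some minimum
spanning tree of the Hamming-distance graph (Kruskal sweep retaining
ties), plus edges within `epsilon` of the connection threshold
(`epsilon = 0` default, the common tool default; the reference analyses
do not report their setting). `median_joining` then iterates: sequence
triples connected in the current network propose per-site
majority-consensus (quasi-median) vectors — three-way ties generate all
tied characters, with the combinatorics capped at 64 candidates per
triple and a warning — and a proposed median is adopted only when adding
it strictly shortens the total network, so the final network is never
longer than the initial MSN. Median vectors left with degree $< 3$ are
pruned at the end. Adoption proceeds greedily (best candidate first,
re-scoring a short list of runners-up after each adoption); this is a
heuristic in the same spirit as the original algorithm, not a guaranteed
Steiner minimum. Character weights are uniform. Observed haplotypes are
never removed, and every edge weight equals the Hamming distance between
its endpoint sequences. Networks export to GraphML (lossless via igraph)
or a TSV edge list with node attributes (count, group composition,
inferred flag).

## Divergence time

`net_divergence` computes the mean between-species per-site difference
$d_{xy}$ and the net divergence $d_a = d_{xy} - (d_x + d_y)/2$;
`divergence_years` converts via $t = d_a/(2\mu)$ with the per-year rate.
This moment estimator is the package's deliberate desk-scale substitute
for full isolation-with-migration machinery (six demographic parameters,
Metropolis-coupled MCMC), which is out of scope; the simulation suite
validates it by parameter recovery (mean within 25% of a simulated
20,600-year split under no migration) instead of by posterior
comparison. Its known biases are documented rather than corrected:
migration biases it downward, as does a demographic expansion younger
than the split (within-species coalescence is pushed back past the
expansion, inflating the subtracted term); negative $d_a$ is reported
with an undefined-time flag. Replicate spread over simulations, not a
posterior, is its uncertainty statement.

## Predation statistics

Prey mortality is the proportion missing $p = (P_I - P_T)/P_I$, arcsine
square-root transformed for analysis. The predation rate coefficient
$K = \ln(P_I/P_T)/(XT)$ (per predator per hour) is the exponential decay
rate implied by the predation term $dP/dt = -KXP$ — the standard closed
form given initial and final prey counts, predator number and trial
duration; its magnitudes match reported invertebrate
(order $10^{-2}$ at 24 h) and fish (order 1 at 1 h) coefficients.
$K$ is computed in predator treatments only
($X \ge 1$), is undefined at total extirpation ($P_T = 0$; no continuity
correction is invented), and — being a ratio — is identical whether
counts are per experimental unit or per liter. `summarize_cells` reports
mean ± SE per species-by-treatment cell. The factorial and nested
ANOVAs of the original experiments are routine statistics left to
standard tools.

## Numerical and testing choices

* Optimizer: Nelder–Mead, `reltol = 1e-10`, 500 iterations, three
  starts; parameters squared inside the objective to enforce bounds.
* Quantiles: R type 7 everywhere (documented in `tau_ci`).
* Permutation p-values: $+1$ correction for the two permutation tests;
  plain fraction for the parametric-bootstrap SSD test, so a perfect fit
  yields exactly 1.
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; fixed seed means byte-identical output.
* Simulation sizes in the test suite are desk-scale choices balancing
  Monte-Carlo error against runtime: 2000 replicates for the generator
  moments; 100 replicates at $n = 100$ with $B = 200$ bootstrap samples
  for expansion recovery and CI coverage; 200 outer replicates at
  $B = 200$ for SSD-p uniformity; 200 structureless datasets at 199
  permutations for AMOVA size; 100 replicates for divergence recovery.

## Known limitations

* The mismatch $\hat\tau$ upward tendency and the expansion-induced
  downward bias of the net-divergence clock are properties of the
  estimators, documented and measured, not corrected.
* AMOVA population labels in simulated data carry no true structure;
  among-population components are only exercised for size, not power.
* The median-joining search is a capped greedy heuristic; on
  deeply-diverged data (tens of mutational steps between clusters) the
  inferred medians summarize long paths rather than reconstruct
  plausible ancestors — as with any median-joining tool, the method is
  meant for shallow intraspecific divergence.
* gsi values from the analysis scripts are computed on the *true*
  simulated genealogies (or NJ reconstructions), not on likelihood
  trees; with real data the tree uncertainty is extra.
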