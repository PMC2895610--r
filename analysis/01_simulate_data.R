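#!/usr/bin/env Rscript
# Generate a synthetic two-species multilocus dataset with the structure
# of the field study: one mitochondrial marker (ND2, 631 bp, duplicated to
# two identical copies per individual) and three nuclear markers (HSP90
# 669 bp, F6F12 433 bp, G6G12 534 bp; two phased allele copies per
# individual), 16 individuals per species spread over 4 population labels
# per species, under a two-population isolation history (divergence
# 20,600 years ago, no migration) with a sudden expansion.
#
# Writes FASTA + metadata TSV + true-genealogy Newick per marker and a
# scenario provenance JSON under results/sim/.

suppressPackageStartupMessages({
  library(idpopgen)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 7L
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

n_ind <- 16L          # individuals per species
n_pops <- 4L          # population labels per species
t_exp_years <- 11405  # expansion age anchoring the nuclear scenarios

## The expansion age is a mitochondrial estimate in mitochondrial
## mutational units (tau = 4.765); the nuclear markers get the same
## expansion anchored in years, converted into each marker's own
## mutational units (tau = 2 u t generations).
nuc_tau <- function(L) 2 * (1.05e-7 / 5 * L) * (t_exp_years * 5)
markers <- list(
  ND2   = list(L = 631L, mu_year = 3.3e-6,  ploidy = 1L, tau = 4.765),
  HSP90 = list(L = 669L, mu_year = 1.05e-7, ploidy = 2L, tau = nuc_tau(669)),
  F6F12 = list(L = 433L, mu_year = 1.05e-7, ploidy = 2L, tau = nuc_tau(433)),
  G6G12 = list(L = 534L, mu_year = 1.05e-7, ploidy = 2L, tau = nuc_tau(534))
)

species_names <- c(A = "parvula", B = "retrocurva")

for (mk in names(markers)) {
  p <- markers[[mk]]
  n_copies <- n_ind * p$ploidy
  sc <- coalescent_scenario(
    n_per_pop = c(n_copies, n_copies),
    theta0 = 1, theta1 = 1000, tau_expansion = p$tau,
    t_div_years = 20600, mig_rate = 0,
    mu_site_per_gen = p$mu_year / 5, mu_site_per_year = p$mu_year,
    L = p$L, gens_per_year = 5, seed = seed)
  sim <- simulate_two_population(sc, seed = seed + match(mk, names(markers)))
  aln <- sim$aln
  meta <- aln$meta
  ## label individuals, allele copies and populations (copies of one
  ## individual stay together; populations are labels over a panmictic
  ## species sample)
  within <- stats::ave(seq_len(nrow(meta)), meta$species, FUN = seq_along)
  ind <- ceiling(within / p$ploidy)
  meta$individual_id <- sprintf("%s_i%02d", species_names[meta$species], ind)
  meta$allele_copy <- if (p$ploidy == 2) c("a", "b")[1 + (within + 1) %% 2]
                      else "a"
  meta$species <- species_names[meta$species]
  meta$population <- sprintf("%s_pop%d", substr(meta$species, 1, 1),
                             1 + (ind - 1) %% n_pops)
  meta$marker <- mk
  meta$sample_id <- paste0(meta$individual_id, "_", meta$allele_copy)
  seqs <- aln$seq
  names(seqs) <- meta$sample_id
  relabeled <- labeled_alignment(seqs, meta)
  if (p$ploidy == 1L) {
    ## haploid marker: tree tips keep one copy; the alignment used in
    ## multilocus analyses carries the duplicated a/b convention
    dup <- duplicate_haploid_copies(relabeled)
    write_alignment(dup, file.path(outdir, paste0(mk, ".fa")),
                    file.path(outdir, paste0(mk, ".tsv")))
    write_alignment(relabeled, file.path(outdir, paste0(mk, "_haploid.fa")),
                    file.path(outdir, paste0(mk, "_haploid.tsv")))
  } else {
    write_alignment(relabeled, file.path(outdir, paste0(mk, ".fa")),
                    file.path(outdir, paste0(mk, ".tsv")))
  }
  tr <- sim$genealogy
  tr$tip.label <- meta$sample_id[match(tr$tip.label, aln$meta$sample_id)]
  write_newick(tr, file.path(outdir, paste0(mk, "_genealogy.nwk")))
  write_json(c(sc[names(sc) != "seed"], list(seed = seed, marker = mk)),
             file.path(outdir, paste0(mk, "_scenario.json")),
             auto_unbox = TRUE, digits = NA)
  cat(sprintf("%-6s %d bp, %d sequences, %d segregating sites\n",
              mk, p$L, length(relabeled$seq), tajimas_d(relabeled)$S))
}
cat("wrote", outdir, "\n")
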