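#!/usr/bin/env Rscript
# Median-joining haplotype networks for the simulated mitochondrial data
# and the concatenated nuclear data. Under a recent split the two species
# are expected to share central (ancestral) haplotypes while private
# haplotypes sit at the tips of the network.

suppressPackageStartupMessages(library(idpopgen))
dir.create("results", showWarnings = FALSE)

read_sim <- function(mk) read_alignment(file.path("results/sim",
                                                  paste0(mk, ".fa")),
                                        file.path("results/sim",
                                                  paste0(mk, ".tsv")))

concat <- function(alns) {
  ids <- Reduce(intersect, lapply(alns, function(a) a$meta$sample_id))
  seqs <- sapply(ids, function(id)
    paste(vapply(alns, function(a) unname(a$seq[id]), ""), collapse = ""))
  labeled_alignment(seqs, within(alns[[1]]$meta[match(ids, alns[[1]]$meta$sample_id), ],
                                 marker <- "nuclear_concat"))
}

sets <- list(
  mito = read_sim("ND2_haploid"),
  nuclear = concat(lapply(c("HSP90", "F6F12", "G6G12"), read_sim))
)

for (nm in names(sets)) {
  h <- collapse_haplotypes(sets[[nm]])
  net <- suppressWarnings(median_joining(h, epsilon = 0))
  export_network(net, file.path("results", paste0("network_", nm, ".graphml")),
                 "graphml")
  export_network(net, file.path("results", paste0("network_", nm, "_edges.tsv")),
                 "tsv_edges")
  shared <- sum(apply(h$composition, 1, function(x) {
    sp <- sub(":.*", "", colnames(h$composition))
    length(unique(sp[x > 0])) > 1
  }))
  cat(sprintf("%-8s %d haplotypes (%d shared between species), %d medians, total length %d\n",
              nm, length(h$haplotypes), shared, sum(net$nodes$inferred),
              sum(net$edges$weight)))
}
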