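#' Tajima's D and summary diversity statistics
#'
#' Standard Tajima (1989) test statistic
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` contrasting mean pairwise
#' diversity with the scaled number of segregating sites. Sites are counted
#' after complete deletion of columns containing gaps or `N`.
#'
#' @param aln A [labeled_alignment()] with `n >= 4` recommended.
#' @return Object of class `neutrality_stats`: list with `tajima_D`
#'   (`NA` with `D_defined = FALSE` when `S = 0`), `S`, `pi`, `n` and
#'   `sites_used`.
#' @export
tajimas_d <- function(aln) {
  d <- pairwise_differences(aln, "complete_deletion")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 sequences")
  m <- .aln_matrix(aln)
  m <- m[, colSums(m == 0L) == 0L, drop = FALSE]
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1L))
  pi <- mean(d[upper.tri(d)])
  if (S == 0L) {
    return(structure(list(tajima_D = NA_real_, D_defined = FALSE, S = 0L,
                          pi = pi, n = n,
                          sites_used = attr(d, "sites_used")),
                     class = "neutrality_stats"))
  }
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(tajima_D = D, D_defined = TRUE, S = S, pi = pi, n = n,
                 sites_used = attr(d, "sites_used")),
            class = "neutrality_stats")
}

#' Four-gamete test for recombination
#'
#' Flags every pair of biallelic segregating sites at which all four
#' haplotype combinations occur; under infinite sites without
#' recombination no pair can show all four gametes. Non-biallelic
#' segregating sites are skipped and reported. Columns containing gaps or
#' `N` are removed first (complete deletion); site indices are 1-based
#' positions in the input alignment.
#'
#' @param aln A [labeled_alignment()].
#' @return List with `incompatible_pairs` (two-column matrix of 1-based
#'   site positions), `n_segregating`, `n_biallelic` and
#'   `skipped_sites` (positions of non-biallelic segregating sites).
#' @export
four_gamete_test <- function(aln) {
  m <- .aln_matrix(aln)
  keep <- colSums(m == 0L) == 0L
  m <- m[, keep, drop = FALSE]
  pos <- which(keep)
  nalleles <- apply(m, 2, function(col) length(unique(col)))
  seg <- which(nalleles > 1L)
  bi <- which(nalleles == 2L)
  skipped <- pos[setdiff(seg, bi)]
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("site1", "site2")))
  if (length(bi) >= 2L) {
    ## binary encoding per biallelic site
    bm <- vapply(bi, function(j) as.integer(m[, j] == m[1, j]),
                 integer(nrow(m)))
    idx <- utils::combn(seq_along(bi), 2)
    hit <- apply(idx, 2, function(ij) {
      length(unique(2L * bm[, ij[1]] + bm[, ij[2]])) == 4L
    })
    if (any(hit))
      pairs <- cbind(site1 = pos[bi[idx[1, hit]]],
                     site2 = pos[bi[idx[2, hit]]])
  }
  list(incompatible_pairs = pairs, n_segregating = length(seg),
       n_biallelic = length(bi), skipped_sites = skipped)
}
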