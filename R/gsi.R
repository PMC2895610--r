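#' Read a rooted tree from a Newick file or string
#'
#' Thin validated wrapper around [ape::read.tree()]: polytomies are
#' allowed, tip labels must be unique, and the tree is treated as rooted
#' as written.
#'
#' @param path Path to a Newick file, or a Newick string (detected by a
#'   terminal `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";\\s*$", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("parse error: not a valid Newick tree")
  if (anyDuplicated(tr$tip.label))
    stop("parse error: duplicate tip labels")
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Neighbor-joining tree with explicit rooting
#'
#' Saitou-Nei agglomeration (via [ape::nj()]) over a pairwise-difference
#' matrix, rooted either at the midpoint of the longest path or on a
#' declared outgroup. Provided as self-contained plumbing so the gsi stage
#' can run without an external likelihood tree.
#'
#' @param d A `pdiff_matrix` or symmetric distance matrix with >= 3 taxa.
#' @param rooting `"midpoint"` (default) or `"outgroup"`.
#' @param outgroup Tip label, required when `rooting = "outgroup"`.
#' @return A rooted `phylo`.
#' @export
neighbor_joining <- function(d, rooting = c("midpoint", "outgroup"),
                             outgroup = NULL) {
  rooting <- match.arg(rooting)
  dm <- as.matrix(unclass(d))
  storage.mode(dm) <- "double"
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  if (rooting == "midpoint") phangorn::midpoint(tr)
  else {
    if (is.null(outgroup) || !outgroup %in% tr$tip.label)
      stop("outgroup label not in tree")
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
}

## Uniting-node statistic: gs = n / sum(deg_u - 2) over all internal nodes
## on paths from the group tips through their MRCA, where n = k - 1 is the
## minimum node count needed to unite k tips; degree counts children plus
## one for the parent (the root has no parent). For any monophyletic group
## whose MRCA is below the root the sum telescopes to k - 1, so gs = 1 on
## arbitrary multifurcating trees.
.gsi_raw <- function(parent, nchild, is_root, tip_idx) {
  k <- length(tip_idx)
  ## climb every group tip to the root, counting visits; the uniting set is
  ## every internal node visited before reaching the MRCA (the first node
  ## from which all k tips descend) plus the MRCA itself
  visits <- integer(length(parent))
  for (tp in tip_idx) {
    v <- parent[tp]
    while (v != 0L) {
      visits[v] <- visits[v] + 1L
      if (visits[v] == k) break     # at the MRCA; nodes above are not needed
      v <- parent[v]
    }
  }
  mrca <- which(visits == k)
  mrca <- if (length(mrca)) mrca[1] else which(is_root)
  ## nodes visited at least once, minus ancestors of the MRCA
  uniting <- which(visits > 0L)
  above <- integer(0)
  v <- parent[mrca]
  while (v != 0L) { above <- c(above, v); v <- parent[v] }
  uniting <- setdiff(uniting, above)
  deg <- nchild[uniting] + ifelse(is_root[uniting], 0L, 1L)
  (k - 1) / sum(deg - 2L)
}

.tree_tables <- function(tree) {
  nn <- max(tree$edge)
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nchild <- tabulate(tree$edge[, 1], nn)
  is_root <- parent == 0L & nchild > 0L
  list(parent = parent, nchild = nchild, is_root = is_root,
       ntip = length(tree$tip.label))
}

#' Genealogical sorting index
#'
#' Quantifies the exclusive ancestry of a labelled group on a rooted tree:
#' the raw statistic `gs` is the ratio of the minimum number of nodes
#' needed to unite the group to the (degree-weighted) number of nodes
#' actually uniting it, and `gsi` rescales `gs` between its minimum
#' (`(k-1)/(T-2)`, attained when uniting the group drags in every internal
#' node) and its maximum of 1, so that `gsi = 1` exactly for monophyletic
#' groups and values near 0 indicate panmixia. The statistic is purely
#' topological; branch lengths are ignored. A group comprising all tips or
#' a single tip is trivially exclusive and returns `gsi = 1`.
#'
#' @param tree A rooted `phylo` (polytomies allowed).
#' @param group Character vector of tip labels forming the group.
#' @return Object of class `gsi_result`: list with `group_label`, `gs`,
#'   `gsi` and `n_tips`.
#' @export
gsi <- function(tree, group) {
  if (!length(group)) stop("group must be non-empty")
  miss <- setdiff(group, tree$tip.label)
  if (length(miss))
    stop("label error: group tips absent from tree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tt <- .tree_tables(tree)
  k <- length(group)
  if (k == 1L || k == tt$ntip) {
    return(structure(list(group_label = NA_character_, gs = 1, gsi = 1,
                          n_tips = tt$ntip), class = "gsi_result"))
  }
  tip_idx <- match(group, tree$tip.label)
  gs <- .gsi_raw(tt$parent, tt$nchild, tt$is_root, tip_idx)
  gs_min <- (k - 1) / (tt$ntip - 2)
  gsi_val <- if (gs_min >= 1) 1 else (gs - gs_min) / (1 - gs_min)
  structure(list(group_label = NA_character_, gs = gs,
                 gsi = max(0, min(1, gsi_val)), n_tips = tt$ntip),
            class = "gsi_result")
}

#' @export
print.gsi_result <- function(x, ...) {
  cat("gsi =", format(x$gsi, digits = 4),
      "(gs =", format(x$gs, digits = 4), ")")
  if (!is.null(x$p)) cat("  p =", format(x$p, digits = 4))
  cat("\n")
  invisible(x)
}

#' Permutation test for the genealogical sorting index
#'
#' Permutes the group assignment uniformly over tips (keeping the group
#' size), recomputes `gsi`, and reports
#' `p = (count >= observed + 1) / (n_perm + 1)`.
#'
#' @inheritParams gsi
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Optional integer seed.
#' @return A `gsi_result` with `p` and `n_perm` attached.
#' @export
gsi_test <- function(tree, group, n_perm = 999, seed = NULL) {
  obs <- gsi(tree, group)
  tt <- .tree_tables(tree)
  k <- length(group)
  if (k == tt$ntip || k == 1L) {      # statistic invariant under permutation
    obs$p <- 1
    obs$n_perm <- n_perm
    return(obs)
  }
  gs_min <- (k - 1) / (tt$ntip - 2)
  obs$p <- with_seed(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      tip_idx <- sample.int(tt$ntip, k)
      gs <- .gsi_raw(tt$parent, tt$nchild, tt$is_root, tip_idx)
      g <- if (gs_min >= 1) 1 else (gs - gs_min) / (1 - gs_min)
      if (g >= obs$gsi - 1e-12) ge <- ge + 1L
    }
    (ge + 1) / (n_perm + 1)
  })
  obs$n_perm <- n_perm
  obs
}

#' gsi under repeated balanced subsampling
#'
#' When one group is over-represented, whole individuals (both allele
#' copies) are randomly pruned from the larger group until the groups hold
#' equally many individuals; `gsi` (with permutation test) is recomputed on
#' each pruned tree and summarized over subsamples.
#'
#' @param tree A rooted `phylo` whose tips are sample ids.
#' @param meta Data frame with columns `sample_id`, `individual_id` and the
#'   grouping column; one row per tip.
#' @param group_field Metadata column defining the two groups (default
#'   `"species"`).
#' @param n_subsamples Number of random prunings.
#' @param n_perm Permutations per subsample (0 to skip testing).
#' @param seed Optional integer seed.
#' @return Object of class `gsi_balanced`: list with `per_subsample` (data
#'   frame of group, gsi, p per subsample), `summary` (median gsi and IQR
#'   per group) and `kept_tips` (tip labels retained in each subsample).
#' @export
gsi_balanced <- function(tree, meta, group_field = "species",
                         n_subsamples = 20, n_perm = 0, seed = NULL) {
  meta <- meta[match(tree$tip.label, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("tree tips missing from metadata")
  grp <- meta[[group_field]]
  glev <- unique(grp)
  if (length(glev) != 2L) stop("need exactly two groups")
  ind <- unique(meta[, c("individual_id", group_field)])
  sizes <- table(ind[[group_field]])
  k <- min(sizes)
  with_seed(seed, {
    subs <- lapply(seq_len(n_subsamples), function(s) {
      keep_ind <- unlist(lapply(split(ind$individual_id, ind[[group_field]]),
                                function(ids) if (length(ids) == k) ids
                                else sample(ids, k)))
      keep_tip <- meta$sample_id[meta$individual_id %in% keep_ind]
      tr <- ape::keep.tip(tree, keep_tip)
      sub <- meta[meta$sample_id %in% keep_tip, , drop = FALSE]
      tab <- do.call(rbind, lapply(glev, function(g) {
        tips <- sub$sample_id[sub[[group_field]] == g]
        res <- if (n_perm > 0) gsi_test(tr, tips, n_perm = n_perm)
               else gsi(tr, tips)
        data.frame(subsample = s, group = g, gsi = res$gsi, gs = res$gs,
                   p = if (is.null(res$p)) NA_real_ else res$p,
                   stringsAsFactors = FALSE)
      }))
      list(tab = tab, tips = keep_tip)
    })
    kept <- lapply(subs, `[[`, "tips")
    per <- do.call(rbind, lapply(subs, `[[`, "tab"))
    summ <- do.call(rbind, lapply(glev, function(g) {
      v <- per$gsi[per$group == g]
      data.frame(group = g, median_gsi = stats::median(v),
                 iqr = stats::IQR(v),
                 median_p = stats::median(per$p[per$group == g]),
                 stringsAsFactors = FALSE)
    }))
    structure(list(per_subsample = per, summary = summ,
                   kept_tips = kept, n_individuals_per_group = k),
              class = "gsi_balanced")
  })
}

#' @export
print.gsi_balanced <- function(x, ...) {
  cat("gsi over", max(x$per_subsample$subsample),
      "balanced subsamples (", x$n_individuals_per_group,
      "individuals/group )\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
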