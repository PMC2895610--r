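## Hamming distances between haplotype sequences (no missing data)
.hap_dist <- function(seqs) {
  ch <- strsplit(seqs, "", fixed = TRUE)
  n <- length(ch)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(ch[[i]] != ch[[j]])
  d
}

## MSN edge list over a distance matrix: an edge (i, j, w) is retained iff
## i and j fall in different components of the graph of all pairs closer
## than w - epsilon; epsilon = 0 keeps exactly the edges occurring in some
## minimum spanning tree (Kruskal sweep retaining ties). Implemented as a
## single ascending sweep with per-weight-class component snapshots.
.msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- as.integer(d[upper.tri(d)])
  uw <- sort(unique(w))
  ## snapshots[k, ] = components using all edges of weight <= uw[k - 1]
  snap <- matrix(0L, length(uw) + 1L, n)
  comp <- seq_len(n)
  snap[1L, ] <- comp
  by_class <- split(seq_along(w), factor(w, levels = uw))
  for (k in seq_along(uw)) {
    for (e in by_class[[k]]) {
      a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
      if (a != b) comp[comp == b] <- a
    }
    snap[k + 1L, ] <- comp
  }
  ## state "< w - epsilon" = classes <= w - epsilon - 1 (integer weights)
  idx <- findInterval(w - epsilon - 1L, uw) + 1L
  keep <- snap[cbind(idx, pairs[, 1])] != snap[cbind(idx, pairs[, 2])]
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
             weight = w[keep])
}

.build_network <- function(seqs, inferred, counts, composition, epsilon) {
  d <- .hap_dist(seqs)
  edges <- .msn_edges(d, epsilon)
  ids <- ifelse(inferred, paste0("mv", cumsum(inferred)),
                paste0("H", cumsum(!inferred)))
  structure(list(
    nodes = data.frame(id = ids, sequence = seqs, count = counts,
                       inferred = inferred, stringsAsFactors = FALSE),
    edges = data.frame(from = ids[edges$from], to = ids[edges$to],
                       weight = edges$weight, stringsAsFactors = FALSE),
    composition = composition, epsilon = epsilon),
    class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplotype network:", sum(!x$nodes$inferred), "observed +",
      sum(x$nodes$inferred), "median nodes,", nrow(x$edges),
      "edges, total length", sum(x$edges$weight),
      "(epsilon =", x$epsilon, ")\n")
  invisible(x)
}

#' Minimum spanning network of haplotypes
#'
#' All edges occurring in some minimum spanning tree of the
#' Hamming-distance graph, plus (for `epsilon > 0`) edges within `epsilon`
#' steps of the connection threshold. Edge weights are mutational steps
#' (Hamming distance between the endpoint sequences).
#'
#' @param h A `haplotype_table` from [collapse_haplotypes()], or a
#'   character vector of unique aligned sequences.
#' @param epsilon Non-negative integer relaxation of the connection
#'   threshold (0 = strict, the default used by network-drawing practice).
#' @return Object of class `haplo_network`: list with `nodes` (id,
#'   sequence, count, inferred flag), `edges` (from, to, weight),
#'   `composition` and `epsilon`.
#' @export
minimum_spanning_network <- function(h, epsilon = 0) {
  stopifnot(epsilon >= 0)
  if (inherits(h, "haplotype_table")) {
    seqs <- unname(h$haplotypes); counts <- h$counts; comp <- h$composition
  } else {
    seqs <- unname(as.character(h))
    if (anyDuplicated(seqs)) stop("haplotypes must be unique")
    counts <- rep(1L, length(seqs)); comp <- NULL
  }
  if (length(seqs) < 2) stop("need at least 2 haplotypes")
  .build_network(seqs, rep(FALSE, length(seqs)), counts, comp, epsilon)
}

## all per-site majority-consensus candidates of a sequence triple;
## three-way ties generate every tied character (quasi-median), with the
## combinatorics capped
.triple_medians <- function(s1, s2, s3, max_candidates = 64) {
  a <- strsplit(c(s1, s2, s3), "", fixed = TRUE)
  x <- a[[1]]; y <- a[[2]]; z <- a[[3]]
  L <- length(x)
  ## per-site majority; a three-way tie keeps all three characters
  maj <- ifelse(x == y | x == z, x, ifelse(y == z, y, NA))
  opts <- as.list(maj)
  for (p in which(is.na(maj))) opts[[p]] <- c(x[p], y[p], z[p])
  nopt <- lengths(opts)
  total <- prod(nopt)
  if (total > max_candidates) {
    warning("quasi-median combinatorics capped at ", max_candidates,
            " candidates")
    tie_sites <- which(nopt > 1)
    keep_ties <- tie_sites[seq_len(max(0, floor(log(max_candidates, 3))))]
    for (p in setdiff(tie_sites, keep_ties)) opts[[p]] <- opts[[p]][1]
  }
  apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

#' Median-joining haplotype network
#'
#' Iterative construction in the spirit of the Bandelt median-joining
#' algorithm: starting from the minimum spanning network, sequence triples
#' connected in the current network propose per-site majority-consensus
#' (quasi-median) vectors; a proposed median is adopted when adding it
#' strictly reduces the total network length, and the process repeats to a
#' fixed point. Median vectors left with degree below 3 are pruned
#' (rebuilding the network after each removal). Observed haplotypes are
#' never removed.
#'
#' @inheritParams minimum_spanning_network
#' @param max_iter Iteration cap; exceeding it raises an error carrying the
#'   partial result as attribute `partial`.
#' @param max_candidates Cap on quasi-median candidates per triple.
#' @return A `haplo_network` whose inferred nodes are the added median
#'   vectors.
#' @export
median_joining <- function(h, epsilon = 0, max_iter = 25,
                           max_candidates = 64) {
  base <- minimum_spanning_network(h, epsilon)
  seqs <- base$nodes$sequence
  counts <- base$nodes$count
  inferred <- base$nodes$inferred
  D <- .hap_dist(seqs)                       # extended as medians join
  seq_ints <- function(s) {
    m <- t(vapply(strsplit(s, "", fixed = TRUE),
                  function(x) match(x, c("A", "C", "G", "T", "-", "N")),
                  integer(nchar(s[1]))))
    storage.mode(m) <- "integer"
    m
  }
  M <- seq_ints(seqs)
  cur <- sum(.msn_edges(D, epsilon)$weight)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    edges <- .msn_edges(D, epsilon)
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj <- adj | t(adj)
    cand <- character(0)
    for (v in seq_len(n)) {
      nb <- which(adj[v, ])
      if (length(nb) >= 2) {
        prs <- utils::combn(nb, 2)
        for (q in seq_len(ncol(prs)))
          cand <- c(cand, .triple_medians(seqs[v], seqs[prs[1, q]],
                                          seqs[prs[2, q]],
                                          max_candidates))
      }
    }
    cand <- setdiff(unique(cand), seqs)
    if (!length(cand)) { converged <- TRUE; break }
    ## greedy within-round adoption: score every candidate against the
    ## current network, repeatedly add the best improver (rescoring a
    ## short list of runners-up against the grown network), so each
    ## accepted median strictly shortens the network at adoption time
    CM <- seq_ints(cand)
    rows <- lapply(seq_along(cand), function(ci) colSums(t(M) != CM[ci, ]))
    lens <- vapply(seq_along(cand), function(ci) {
      D2 <- rbind(cbind(D, rows[[ci]]), c(rows[[ci]], 0L))
      sum(.msn_edges(D2, epsilon)$weight)
    }, 0)
    added <- FALSE
    pool <- order(lens)[lens[order(lens)] < cur]
    while (length(pool)) {
      scored <- utils::head(pool, 25L)
      best_len <- cur
      best <- NULL
      for (ci in scored) {
        row <- colSums(t(M) != CM[ci, ])
        D2 <- rbind(cbind(D, row), c(row, 0L))
        len <- sum(.msn_edges(D2, epsilon)$weight)
        if (len < best_len) { best_len <- len; best <- ci; best_row <- row }
      }
      if (is.null(best)) break
      seqs <- c(seqs, cand[best])
      counts <- c(counts, 0L)
      inferred <- c(inferred, TRUE)
      D <- rbind(cbind(D, best_row), c(best_row, 0L))
      M <- rbind(M, CM[best, , drop = FALSE])
      cur <- best_len
      added <- TRUE
      pool <- setdiff(pool, best)
    }
    if (!added) { converged <- TRUE; break }
  }
  if (!converged && any(inferred)) {
    err <- simpleError("median-joining hit the iteration cap; partial result attached")
    attr(err, "partial") <- .build_network(seqs, inferred, counts,
                                           base$composition, epsilon)
    stop(err)
  }
  ## prune obsolete median vectors (degree < 3), rebuilding each time
  repeat {
    edges <- .msn_edges(D, epsilon)
    deg <- tabulate(c(edges$from, edges$to), length(seqs))
    drop <- which(inferred & deg < 3)
    if (!length(drop)) break
    drop <- drop[1]
    seqs <- seqs[-drop]; counts <- counts[-drop]; inferred <- inferred[-drop]
    D <- D[-drop, -drop, drop = FALSE]
  }
  .build_network(seqs, inferred, counts, base$composition, epsilon)
}

#' Convert a haplotype network to an igraph graph
#'
#' Nodes carry `sequence`, `count` and `inferred` attributes; edges carry
#' `weight` (mutational steps).
#'
#' @param net A `haplo_network`.
#' @return An [igraph::graph_from_data_frame()] undirected graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a haplotype network
#'
#' `graphml` writes a GraphML file (losslessly re-importable with
#' [igraph::read_graph()]); `tsv_edges` writes a tab-separated edge list
#' (`from`, `to`, `weight`, endpoint sequences and inferred flags) with
#' deterministic node ordering.
#'
#' @param net A `haplo_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"tsv_edges"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv_edges")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    idx <- match(net$edges$from, net$nodes$id)
    jdx <- match(net$edges$to, net$nodes$id)
    tab <- data.frame(from = net$edges$from, to = net$edges$to,
                      weight = net$edges$weight,
                      from_seq = net$nodes$sequence[idx],
                      to_seq = net$nodes$sequence[jdx],
                      from_inferred = net$nodes$inferred[idx],
                      to_inferred = net$nodes$inferred[jdx])
    tab <- tab[order(tab$from, tab$to), , drop = FALSE]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
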