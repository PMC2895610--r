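test_that("minimum spanning network retains tie edges", {
  n2 <- minimum_spanning_network(c("AAA", "AAT"))
  expect_equal(nrow(n2$edges), 1)
  expect_equal(n2$edges$weight, 1)
  ## three haplotypes mutually at distance 2: full tie triangle at eps = 0
  n3 <- minimum_spanning_network(c("AAC", "TTC", "ATG"))
  expect_equal(nrow(n3$edges), 3)
  expect_true(all(n3$edges$weight == 2))
})

test_that("every MSN edge weight equals the endpoint Hamming distance and
           the MSN spans with minimal weight", {
  set.seed(111)
  for (b in 1:10) {
    seqs <- unique(rand_seqs(6, 8))
    if (length(seqs) < 3) next
    net <- minimum_spanning_network(seqs)
    idx <- match(net$edges$from, net$nodes$id)
    jdx <- match(net$edges$to, net$nodes$id)
    ch <- strsplit(net$nodes$sequence, "")
    for (e in seq_len(nrow(net$edges)))
      expect_equal(net$edges$weight[e],
                   sum(ch[[idx[e]]] != ch[[jdx[e]]]))
    ## contains a spanning tree of minimal total weight (brute force)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    expect_equal(sum(igraph::E(mst)$weight),
                 brute_mst_weight(idpopgen:::.hap_dist(seqs)))
    expect_true(igraph::is_connected(g))
  }
})

test_that("median joining adds the Steiner point of the classic triplet", {
  net <- median_joining(c("AAA", "TTA", "TAT"))
  expect_equal(sum(net$nodes$inferred), 1)
  expect_equal(net$nodes$sequence[net$nodes$inferred], "TAA")
  expect_equal(sum(net$edges$weight), 3)
  deg <- table(c(net$edges$from, net$edges$to))
  expect_gte(min(deg[net$nodes$id[net$nodes$inferred]]), 3)
})

test_that("a chain of single-step haplotypes gains no medians", {
  net <- median_joining(c("AAAA", "AAAT", "AATT", "ATTT"))
  expect_equal(sum(net$nodes$inferred), 0)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
})

test_that("median joining never lengthens the network and keeps observed nodes", {
  set.seed(121)
  for (b in 1:12) {
    seqs <- unique(rand_seqs(sample(4:7, 1), 10))
    if (length(seqs) < 3) next
    msn <- minimum_spanning_network(seqs)
    ## random sequences are tie-rich; the quasi-median cap warning is
    ## expected and immaterial to the length bound under test
    mj <- suppressWarnings(median_joining(seqs))
    expect_lte(sum(mj$edges$weight), sum(msn$edges$weight))
    expect_setequal(mj$nodes$sequence[!mj$nodes$inferred], seqs)
    if (any(mj$nodes$inferred)) {
      deg <- table(c(mj$edges$from, mj$edges$to))
      expect_gte(min(deg[mj$nodes$id[mj$nodes$inferred]]), 3)
    }
  }
})

test_that("network export round-trips through GraphML and TSV", {
  net <- median_joining(c("AAA", "TTA", "TAT"))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  expect_equal(igraph::ecount(g2), nrow(net$edges))
  expect_setequal(igraph::V(g2)$inferred, net$nodes$inferred)
  g1 <- as_igraph(net)
  expect_true(igraph::isomorphic(g1, g2))
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv_edges")
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), nrow(net$edges))
  expect_equal(sort(tab$weight), sort(net$edges$weight))
})
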