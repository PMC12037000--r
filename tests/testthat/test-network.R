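# cocitation fixture: citers CA, CB cite publications mentioning pairs of
# biobanks
cocite_fixture <- function() {
  cp <- tiny_corpus()
  docs <- cp$documents
  extra <- docs[rep(3, 3), ]
  extra$id <- c("CA", "CB", "CC")
  extra$author_ids <- replicate(3, character(0), simplify = FALSE)
  extra$affil_institutions <- replicate(3, character(0), simplify = FALSE)
  extra$affil_countries <- replicate(3, character(0), simplify = FALSE)
  extra$mesh_conditions <- replicate(3, character(0), simplify = FALSE)
  extra$mesh_categories <- replicate(3, character(0), simplify = FALSE)
  extra$rcdc_categories <- replicate(3, character(0), simplify = FALSE)
  docs <- rbind(docs, extra)
  # CA cites P3 (mentions B1) and P5 (mentions B2): cocitation B1-B2
  # CB cites P4 (B1) and P5 (B2): second cocitation B1-B2
  # CC cites only P3: no pair
  cit <- rbind(cp$citations,
               data.frame(citing_id = c("CA", "CA", "CB", "CB", "CC"),
                          cited_id = c("P3", "P5", "P4", "P5", "P3")))
  bif_corpus(docs, cp$mentions, cit, cp$biobanks, cp$funding, 2024)
}

test_that("cocitation weights count co-citing articles with threshold semantics", {
  cp <- cocite_fixture()
  # P4 also cites P5, so three articles co-cite B1 and B2 publications?
  # P4 itself mentions B1 and cites P5 (mentions B2): it only cites B2's
  # publication, not B1's, so it contributes no pair.
  g2 <- build_cocitation(cp, min_weight = 2)
  expect_equal(unname(graph_weight_map(g2)["B1~B2"]), 2)
  expect_equal(igraph::ecount(g2), 1L)

  # raising the threshold above the weight drops the edge
  g3 <- build_cocitation(cp, min_weight = 3)
  expect_equal(igraph::ecount(g3), 0L)

  # a corpus where no article cites two biobanks' papers is edgeless
  g0 <- build_cocitation(tiny_corpus(), min_weight = 1)
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("cocitation weights equal brute-force pair enumeration", {
  for (s in 11:14) {
    cp <- random_fixture(s)$corpus
    g <- build_cocitation(cp, min_weight = 1)
    expect_equal(graph_weight_map(g)[order(names(graph_weight_map(g)))],
                 oracle_cocitation_weights(cp)[
                   order(names(oracle_cocitation_weights(cp)))],
                 label = paste("seed", s))
  }
})

test_that("deleting a biobank never increases remaining cocitation weights", {
  cp <- random_fixture(15)$corpus
  w_full <- oracle_cocitation_weights(cp)
  drop_bb <- cp$biobanks$id[1]
  cp2 <- cp
  cp2$mentions <- cp$mentions[cp$mentions$biobank_id != drop_bb, ]
  g2 <- build_cocitation(cp2, min_weight = 1)
  w2 <- graph_weight_map(g2)
  shared <- intersect(names(w2), names(w_full))
  expect_true(all(w2[shared] <= w_full[shared]))
})

test_that("community detection splits planted cliques and handles edgeless graphs", {
  # two 5-cliques joined by one edge
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  g <- igraph::add_edges(g, c(1, 6))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("n", 1:10)
  part <- detect_communities(g, seed = 7)
  expect_equal(length(unique(part$membership)), 2L)
  expect_equal(length(unique(part$membership[1:5])), 1L)
  expect_equal(length(unique(part$membership[6:10])), 1L)
  expect_gt(part$modularity, 0.3)

  # deterministic under seed
  part2 <- detect_communities(g, seed = 7)
  expect_identical(part$membership, part2$membership)

  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- letters[1:4]
  p0 <- detect_communities(g0, seed = 1)
  expect_equal(length(unique(p0$membership)), 4L)
  expect_equal(p0$modularity, 0)
})

test_that("planted-partition graphs are recovered with NMI above 0.9", {
  set.seed(55)
  sizes <- rep(25, 4)
  pm <- matrix(0.02, 4, 4); diag(pm) <- 0.5
  g <- igraph::sample_sbm(100, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- paste0("v", 1:100)
  igraph::E(g)$weight <- 1
  part <- detect_communities(g, seed = 3)
  truth <- stats::setNames(rep(1:4, each = 25), igraph::V(g)$name)
  expect_gt(partition_nmi(part, truth), 0.9)
})

test_that("NMI matches direct entropy arithmetic and its invariances", {
  # worked 4-node contingency table: partition (1,1,2,2) vs labels
  # (a,a,a,b) -> joint p = [[1/2,0],[1/4,1/4]]
  memb <- stats::setNames(c(1, 1, 2, 2), paste0("n", 1:4))
  labs <- stats::setNames(c("a", "a", "a", "b"), paste0("n", 1:4))
  hx <- -2 * 0.5 * log(0.5)
  hy <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  mi <- 0.5 * log(0.5 / (0.5 * 0.75)) + 0.25 * log(0.25 / (0.5 * 0.75)) +
    0.25 * log(0.25 / (0.5 * 0.25))
  expect_equal(partition_nmi(memb, labs), mi / sqrt(hx * hy))
  expect_equal(partition_nmi(memb, labs, normalization = "arithmetic"),
               mi / ((hx + hy) / 2))

  # identical partitions score 1; constant labels score 0
  expect_equal(partition_nmi(memb, stats::setNames(c("x", "x", "y", "y"),
                                                   names(memb))), 1)
  expect_equal(partition_nmi(memb, stats::setNames(rep("z", 4),
                                                   names(memb))), 0)
  # single community vs single category: defined as 1
  expect_equal(partition_nmi(stats::setNames(rep(1, 4), names(memb)),
                             stats::setNames(rep("z", 4), names(memb))), 1)

  # invariant to relabeling either side
  relab <- stats::setNames(c(9, 9, 4, 4), names(memb))
  expect_equal(partition_nmi(relab, labs), partition_nmi(memb, labs))

  # range [0, 1] on random partitions
  set.seed(8)
  for (i in 1:20) {
    m <- stats::setNames(sample(1:3, 12, TRUE), paste0("k", 1:12))
    l <- stats::setNames(sample(letters[1:4], 12, TRUE), names(m))
    v <- partition_nmi(m, l)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("arithmetic-mean NMI agrees with the igraph implementation", {
  set.seed(17)
  for (i in 1:10) {
    m <- stats::setNames(sample(1:4, 30, TRUE), paste0("k", 1:30))
    l <- stats::setNames(sample(1:3, 30, TRUE), names(m))
    expect_equal(partition_nmi(m, l, normalization = "arithmetic"),
                 igraph::compare(m, l[names(m)], method = "nmi"),
                 tolerance = 1e-10)
  }
})

test_that("graph export writes GraphML and a weighted edge list", {
  cp <- cocite_fixture()
  g <- build_cocitation(cp, min_weight = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  el <- withr::local_tempfile(fileext = ".tsv")
  write_graph_files(g, graphml = gml, edgelist = el)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  tab <- utils::read.delim(el)
  expect_equal(names(tab), c("from", "to", "weight"))
  expect_equal(nrow(tab), igraph::ecount(g))
})
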