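# Biobank cocitation network: two biobanks are cocited when a third
# article cites publications mentioning each of them. Communities are
# detected by modularity optimization and compared to disease-category
# labels through normalized mutual information.

#' Build the biobank cocitation graph
#'
#' For every citing article, the set of distinct biobanks whose mentioning
#' publications it cites contributes +1 to the weight of every pair in the
#' set. Edges with weight below `min_weight` are dropped — the graph keeps
#' only pairs that are cited together repeatedly. Nodes carry their
#' mentioning-publication count and principal disease category.
#'
#' @param corpus a `bif_corpus`.
#' @param min_weight minimum cocitation count for an edge to be kept.
#' @return an undirected weighted [igraph::igraph] with vertex attributes
#'   `n_pubs` and `category`.
#' @export
build_cocitation <- function(corpus, min_weight = 2) {
  mp <- .mentions_of_type(corpus, "publication")
  cit <- corpus$citations
  # biobanks mentioned by each cited publication
  doc2bb <- split(mp$biobank_id, mp$document_id)
  hit <- cit$cited_id %in% names(doc2bb)
  cited_bb <- doc2bb[cit$cited_id[hit]]
  citer <- cit$citing_id[hit]
  # per citing article, distinct cited biobanks
  per_citer <- lapply(split(cited_bb, citer),
                      function(l) unique(unlist(l, use.names = FALSE)))
  pairs <- lapply(per_citer, function(bbs) {
    if (length(bbs) < 2L) return(NULL)
    bbs <- sort(bbs)
    t(utils::combn(bbs, 2L))
  })
  pairs <- do.call(rbind, pairs)
  bb_ids <- corpus$biobanks$id
  if (is.null(pairs) || nrow(pairs) == 0L) {
    g <- igraph::make_empty_graph(n = length(bb_ids), directed = FALSE)
  } else {
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    w <- table(key)
    keep <- as.integer(w) >= min_weight
    ek <- do.call(rbind, strsplit(names(w)[keep], "\r", fixed = TRUE))
    g <- igraph::make_empty_graph(n = length(bb_ids), directed = FALSE)
    if (!is.null(ek) && nrow(ek) > 0L) {
      idx <- rbind(match(ek[, 1], bb_ids), match(ek[, 2], bb_ids))
      g <- igraph::add_edges(g, as.vector(idx))
      igraph::E(g)$weight <- as.integer(w)[keep]
    }
  }
  igraph::V(g)$name <- bb_ids
  np <- .publication_counts(corpus)
  igraph::V(g)$n_pubs <- unname(np[bb_ids])
  igraph::V(g)$category <- vapply(bb_ids, function(b)
    principal_category(corpus, b), character(1))
  g
}

#' Detect communities by modularity optimization
#'
#' Louvain modularity maximization under a fixed seed; an edgeless graph
#' yields singleton communities with modularity 0.
#'
#' @param g weighted undirected graph from [build_cocitation()].
#' @param seed integer seed making the partition deterministic.
#' @return list of class `bif_partition`: `membership` (named vector of
#'   community labels) and `modularity`.
#' @export
detect_communities <- function(g, seed = 7L) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_along(nm), nm)
    return(structure(list(membership = memb, modularity = 0),
                     class = "bif_partition"))
  }
  cl <- .with_seed(seed, igraph::cluster_louvain(g))
  memb <- stats::setNames(igraph::membership(cl), nm)
  structure(list(membership = memb,
                 modularity = igraph::modularity(g, igraph::membership(cl),
                                                 weights = igraph::E(g)$weight)),
            class = "bif_partition")
}

#' Normalized mutual information between a partition and labels
#'
#' NMI computed from the contingency table of community membership versus
#' external category labels, `I(X;Y)` normalized by the geometric mean
#' `sqrt(H(X) H(Y))` of the two entropies (default) or by their arithmetic
#' mean. NMI lies in [0, 1] and is invariant to relabeling either side.
#' When both sides are single-class, both entropies vanish; this
#' degenerate case is defined as 1 (identical trivial partitions).
#'
#' @param partition a `bif_partition` or a named membership vector.
#' @param labels named vector of category labels covering every node in
#'   the partition.
#' @param normalization `"geometric"` (default) or `"arithmetic"` mean of
#'   the entropies.
#' @return NMI in [0, 1].
#' @export
partition_nmi <- function(partition, labels,
                          normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  memb <- if (inherits(partition, "bif_partition")) partition$membership
          else partition
  nodes <- names(memb)
  if (!all(nodes %in% names(labels)))
    stop("labels must cover every node in the partition")
  x <- as.character(memb)
  y <- as.character(labels[nodes])
  n <- length(x)
  tab <- table(x, y)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 && hy == 0) return(1)
  pos <- pxy > 0
  mi <- sum(pxy[pos] * log(pxy[pos] /
                             (outer(px, py)[pos])))
  denom <- switch(normalization,
                  geometric = sqrt(hx * hy),
                  arithmetic = (hx + hy) / 2)
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Export a cocitation graph
#'
#' Writes GraphML and/or a weighted edge list (TSV: from, to, weight).
#'
#' @param g graph from [build_cocitation()].
#' @param graphml,edgelist output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_graph_files <- function(g, graphml = NULL, edgelist = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(edgelist)) {
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el) == 0L)
      el <- data.frame(from = character(0), to = character(0),
                       weight = numeric(0))
    utils::write.table(el, edgelist, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, edgelist)
  }
  invisible(written)
}
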