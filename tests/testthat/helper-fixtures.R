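# Fixtures built in code and independent brute-force oracles used across
# the suite.

# constant feature block for hand-built biobank tables
feature_block <- function(n) {
  as.data.frame(stats::setNames(
    lapply(seq_along(BIOBANK_FEATURES), function(i) rep(0, n)),
    BIOBANK_FEATURES))
}

# hand-built corpus: 2 biobanks, 6 documents, 4 mentions, 3 citations
tiny_corpus <- function() {
  docs <- data.frame(
    id = c("P1", "P2", "P3", "P4", "P5", "G1"),
    doc_type = c("publication", "publication", "publication",
                 "publication", "publication", "grant"),
    year = c(2011L, 2016L, 2018L, 2019L, 2020L, 2021L),
    stringsAsFactors = FALSE
  )
  docs$author_ids <- list(c("p1"), c("p2"), c("t1", "x1"), c("x2"),
                          c("p2", "x3"), character(0))
  docs$affil_institutions <- list("INST_A", "INST_B", "INST_A", "INST_C",
                                  "INST_B", character(0))
  docs$affil_countries <- list("AA", "BB", "AA", "BB", "BB", character(0))
  docs$mesh_conditions <- list(character(0), character(0),
                               c("c_cardio1", "c_rare1"), "c_cardio1",
                               "c_neuro1", character(0))
  docs$mesh_categories <- list(character(0), character(0),
                               c("cardiovascular", "rare"),
                               "cardiovascular", "neurological", character(0))
  docs$rcdc_categories <- list(character(0), character(0), "R_heart",
                               "R_heart", "R_brain", character(0))

  bb <- data.frame(
    id = c("B1", "B2"), name = c("Alpha Bank", "Beta Bank"),
    establishment_year = c(2010L, 2015L),
    host_institution = c("INST_A", "INST_B"),
    host_country = c("AA", "BB"), stringsAsFactors = FALSE
  )
  bb$reference_paper_ids <- list("P1", "P2")
  bb$pi_ids <- list("p1", "p2")
  bb$team_ids <- list(c("p1", "t1"), c("p2", "t2"))
  bb <- cbind(bb, feature_block(2))

  mentions <- data.frame(
    document_id = c("P3", "P4", "P5", "G1"),
    biobank_id = c("B1", "B1", "B2", "B1"),
    location = c("abstract", "title", "abstract", "abstract"),
    stringsAsFactors = FALSE
  )
  citations <- data.frame(
    citing_id = c("P3", "P5", "P4"),
    cited_id = c("P1", "P2", "P5"),
    stringsAsFactors = FALSE
  )
  funding <- data.frame(rcdc_category = c("R_heart", "R_brain", "R_gut"),
                        mean_annual_funding = c(3e9, 2e9, 1e9),
                        stringsAsFactors = FALSE)
  bif_corpus(docs, mentions, citations, bb, funding, reference_year = 2024)
}

# small randomized corpus through the generator
random_fixture <- function(seed, n_biobanks = 10) {
  generate_corpus(
    generator_config(n_biobanks = n_biobanks, mention_meanlog = log(8),
                     mention_sdlog = 0.8, n_countries = 5,
                     n_disease_categories = 5, citer_rate = 1.2),
    seed = seed)
}

# ---- brute-force oracles (independent of the implementation path) ---------

oracle_mention_matrix <- function(corpus, eligible) {
  m <- matrix(0L, length(eligible), length(DOC_TYPES),
              dimnames = list(eligible, DOC_TYPES))
  for (b in eligible) {
    for (ty in DOC_TYPES) {
      n <- 0L
      seen <- character(0)
      for (k in seq_len(nrow(corpus$mentions))) {
        d <- corpus$mentions$document_id[k]
        if (corpus$mentions$biobank_id[k] == b && !(d %in% seen)) {
          i <- which(corpus$documents$id == d)
          if (corpus$documents$doc_type[i] == ty) {
            n <- n + 1L
            seen <- c(seen, d)
          }
        }
      }
      m[b, ty] <- n
    }
  }
  m
}

# publications mentioning biobank b, by full scan
oracle_mentioning_pubs <- function(corpus, b) {
  out <- character(0)
  for (k in seq_len(nrow(corpus$mentions))) {
    if (corpus$mentions$biobank_id[k] != b) next
    d <- corpus$mentions$document_id[k]
    i <- which(corpus$documents$id == d)
    if (corpus$documents$doc_type[i] == "publication") out <- c(out, d)
  }
  unique(out)
}

oracle_cocitation_weights <- function(corpus) {
  pubs_of <- lapply(corpus$biobanks$id, function(b)
    oracle_mentioning_pubs(corpus, b))
  names(pubs_of) <- corpus$biobanks$id
  w <- new.env()
  for (citer in unique(corpus$citations$citing_id)) {
    cited <- corpus$citations$cited_id[corpus$citations$citing_id == citer]
    bbs <- character(0)
    for (b in names(pubs_of))
      if (any(cited %in% pubs_of[[b]])) bbs <- c(bbs, b)
    bbs <- sort(unique(bbs))
    if (length(bbs) < 2) next
    for (i in seq_len(length(bbs) - 1)) for (j in seq(i + 1, length(bbs))) {
      key <- paste(bbs[i], bbs[j], sep = "~")
      w[[key]] <- (if (is.null(w[[key]])) 0 else w[[key]]) + 1
    }
  }
  out <- unlist(as.list(w))
  if (is.null(out)) stats::setNames(numeric(0), character(0)) else out
}

graph_weight_map <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0) return(stats::setNames(numeric(0), character(0)))
  a <- pmin(el$from, el$to); b <- pmax(el$from, el$to)
  stats::setNames(el$weight, paste(a, b, sep = "~"))
}

oracle_reach <- function(corpus, b) {
  pubs <- oracle_mentioning_pubs(corpus, b)
  citers <- character(0)
  for (p in pubs)
    citers <- union(citers,
                    corpus$citations$citing_id[corpus$citations$cited_id == p])
  length(citers)
}

oracle_coauth_shares <- function(corpus, b) {
  i <- which(corpus$biobanks$id == b)
  team <- corpus$biobanks$team_ids[[i]]
  pis <- corpus$biobanks$pi_ids[[i]]
  pubs <- oracle_mentioning_pubs(corpus, b)
  if (length(team) == 0 || length(pubs) == 0) return(NULL)
  nt <- np <- 0
  for (p in pubs) {
    a <- corpus$documents$author_ids[[which(corpus$documents$id == p)]]
    if (length(intersect(a, team)) > 0) nt <- nt + 1
    if (length(intersect(a, pis)) > 0) np <- np + 1
  }
  c(team = nt / length(pubs), pi = np / length(pubs))
}

oracle_principal_category <- function(corpus, b) {
  pubs <- oracle_mentioning_pubs(corpus, b)
  counts <- list()
  for (p in pubs) {
    cats <- unique(corpus$documents$mesh_categories[[
      which(corpus$documents$id == p)]])
    for (cc in cats)
      counts[[cc]] <- (if (is.null(counts[[cc]])) 0 else counts[[cc]]) + 1
  }
  if (length(counts) == 0) return("general-purpose")
  v <- unlist(counts)
  best <- sort(names(v)[v == max(v)])[1]
  best
}
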