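#' @keywords internal
"_PACKAGE"

#' Document types recognised in a corpus
#'
#' The five classes of research documents in which a biobank can be
#' mentioned: publications, grants, patents, clinical trials and public
#' policy documents.
#'
#' @export
DOC_TYPES <- c("publication", "grant", "patent", "clinical_trial", "policy")

#' Names of the fourteen biobank features
#'
#' Binary/ordinal biobank characteristics used as covariates in the
#' feature regression: large cohort sample flag, open-data index class,
#' PI citation-prestige class, population-based flag, genetic markers,
#' GWAS data, whole-genome sequencing, gene-environment data, registries,
#' surveys, follow-up data, medical records, hospital-based flag and
#' general-purpose flag.
#'
#' @export
BIOBANK_FEATURES <- c(
  "sample_size_large", "open_data_index", "pi_prestige",
  "population_based", "genetic_markers", "gwas", "whole_genome_seq",
  "gene_environment", "registries", "surveys", "follow_up",
  "medical_records", "hospital_based", "general_purpose"
)

# ---- internal list-column <-> pipe-string helpers -------------------------

.join_list <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

.split_list <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(as.character(x), "|", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Construct a corpus object
#'
#' A corpus bundles the five tables every analysis consumes: documents,
#' mentions (document-biobank links), directed citation edges, biobank
#' records and per-category funding, together with the reference year used
#' to compute biobank ages.
#'
#' @param documents data.frame with columns `id`, `doc_type`, `year` and
#'   list-columns `author_ids`, `affil_institutions`, `affil_countries`
#'   (parallel), `mesh_conditions`, `mesh_categories` (parallel) and
#'   `rcdc_categories`.
#' @param mentions data.frame with `document_id`, `biobank_id`, `location`.
#' @param citations data.frame with `citing_id`, `cited_id`.
#' @param biobanks data.frame with `id`, `name`, `establishment_year`,
#'   `host_institution`, `host_country`, list-columns
#'   `reference_paper_ids`, `pi_ids`, `team_ids`, and the fourteen feature
#'   columns named in [BIOBANK_FEATURES].
#' @param funding data.frame with `rcdc_category`, `mean_annual_funding`
#'   (mean annual USD).
#' @param reference_year year against which biobank ages are measured.
#' @param validate if `TRUE`, stop on any integrity violation.
#'
#' @return an object of class `bif_corpus`.
#' @export
bif_corpus <- function(documents, mentions, citations, biobanks, funding,
                       reference_year, validate = TRUE) {
  documents <- as.data.frame(documents)
  for (col in c("author_ids", "affil_institutions", "affil_countries",
                "mesh_conditions", "mesh_categories", "rcdc_categories")) {
    if (is.null(documents[[col]])) {
      documents[[col]] <- replicate(nrow(documents), character(0),
                                    simplify = FALSE)
    } else if (!is.list(documents[[col]])) {
      documents[[col]] <- .split_list(documents[[col]])
    }
  }
  biobanks <- as.data.frame(biobanks)
  for (col in c("reference_paper_ids", "pi_ids", "team_ids")) {
    if (!is.list(biobanks[[col]])) biobanks[[col]] <- .split_list(biobanks[[col]])
  }
  dup <- duplicated(mentions[c("document_id", "biobank_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate mention pair(s) collapsed to one")
    mentions <- mentions[!dup, , drop = FALSE]
    rownames(mentions) <- NULL
  }
  x <- structure(
    list(documents = documents, mentions = as.data.frame(mentions),
         citations = as.data.frame(citations), biobanks = biobanks,
         funding = as.data.frame(funding),
         reference_year = as.integer(reference_year)),
    class = "bif_corpus"
  )
  if (validate) {
    rep <- validate_corpus(x)
    if (nrow(rep) > 0L) {
      stop("corpus failed validation:\n",
           paste(utils::capture.output(print(utils::head(rep, 10L))),
                 collapse = "\n"), call. = FALSE)
    }
  }
  x
}

#' @export
print.bif_corpus <- function(x, ...) {
  cat("<bif_corpus>\n")
  cat(sprintf("  documents : %d (%s)\n", nrow(x$documents),
              paste(sprintf("%s=%d", DOC_TYPES,
                            tabulate(factor(x$documents$doc_type,
                                            levels = DOC_TYPES),
                                     length(DOC_TYPES))),
                    collapse = ", ")))
  cat(sprintf("  mentions  : %d\n", nrow(x$mentions)))
  cat(sprintf("  citations : %d\n", nrow(x$citations)))
  cat(sprintf("  biobanks  : %d\n", nrow(x$biobanks)))
  cat(sprintf("  funding   : %d categories\n", nrow(x$funding)))
  cat(sprintf("  reference year: %d\n", x$reference_year))
  invisible(x)
}

# ---- validation ------------------------------------------------------------

.violation <- function(table, row, field, message) {
  data.frame(table = table, row = as.integer(row), field = field,
             message = message, stringsAsFactors = FALSE)
}

#' Validate corpus referential integrity and type invariants
#'
#' Checks every stated invariant: unique document ids, document types from
#' the closed five-set, years within range, mention and citation foreign
#' keys, unique mention pairs, no citation self-loops, establishment years
#' not after the reference year, PI rosters contained in team rosters,
#' complete feature vectors, and non-negative unique funding categories.
#'
#' @param corpus a `bif_corpus` (or a plain list with the same fields).
#' @param year_range allowed document year range.
#' @return data.frame with columns `table`, `row`, `field`, `message`;
#'   zero rows iff the corpus is valid.
#' @export
validate_corpus <- function(corpus, year_range = c(1800L, 2200L)) {
  v <- list()
  docs <- corpus$documents; men <- corpus$mentions
  cit <- corpus$citations; bb <- corpus$biobanks; fun <- corpus$funding

  dup <- which(duplicated(docs$id))
  for (i in dup) v[[length(v) + 1L]] <-
    .violation("documents", i, "id", paste0("duplicate document id '", docs$id[i], "'"))
  bad <- which(!docs$doc_type %in% DOC_TYPES)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("documents", i, "doc_type", paste0("unknown doc_type '", docs$doc_type[i], "'"))
  bad <- which(!is.finite(docs$year) | docs$year < year_range[1] | docs$year > year_range[2])
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("documents", i, "year", paste0("year out of range: ", docs$year[i]))

  doc_ids <- docs$id
  bad <- which(!men$document_id %in% doc_ids)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("mentions", i, "document_id",
               paste0("unknown document_id '", men$document_id[i], "'"))
  bad <- which(!men$biobank_id %in% bb$id)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("mentions", i, "biobank_id",
               paste0("unknown biobank_id '", men$biobank_id[i], "'"))
  bad <- which(duplicated(men[c("document_id", "biobank_id")]))
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("mentions", i, "document_id", "duplicate mention pair")
  bad <- which(!men$location %in% c("title", "abstract", "acknowledgments"))
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("mentions", i, "location",
               paste0("unknown location '", men$location[i], "'"))

  bad <- which(cit$citing_id == cit$cited_id)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("citations", i, "citing_id", "self-loop citation")
  bad <- which(!cit$citing_id %in% doc_ids)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("citations", i, "citing_id",
               paste0("unknown citing_id '", cit$citing_id[i], "'"))
  bad <- which(!cit$cited_id %in% doc_ids)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("citations", i, "cited_id",
               paste0("unknown cited_id '", cit$cited_id[i], "'"))
  bad <- which(duplicated(cit[c("citing_id", "cited_id")]))
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("citations", i, "citing_id", "duplicate citation edge")

  dup <- which(duplicated(bb$id))
  for (i in dup) v[[length(v) + 1L]] <-
    .violation("biobanks", i, "id", paste0("duplicate biobank id '", bb$id[i], "'"))
  bad <- which(bb$establishment_year > corpus$reference_year)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("biobanks", i, "establishment_year",
               "establishment year after reference year")
  for (i in seq_len(nrow(bb))) {
    if (!all(bb$pi_ids[[i]] %in% bb$team_ids[[i]]))
      v[[length(v) + 1L]] <- .violation("biobanks", i, "pi_ids",
                                        "pi_ids not a subset of team_ids")
    if (!all(bb$reference_paper_ids[[i]] %in% doc_ids))
      v[[length(v) + 1L]] <- .violation("biobanks", i, "reference_paper_ids",
                                        "reference paper id does not resolve")
  }
  missing_feat <- setdiff(BIOBANK_FEATURES, names(bb))
  if (length(missing_feat) > 0L && nrow(bb) > 0L) {
    v[[length(v) + 1L]] <- .violation("biobanks", 1L, missing_feat[1],
                                      paste0("missing feature column(s): ",
                                             paste(missing_feat, collapse = ", ")))
  } else {
    for (f in BIOBANK_FEATURES) {
      bad <- which(is.na(bb[[f]]))
      for (i in bad) v[[length(v) + 1L]] <-
        .violation("biobanks", i, f, "missing feature value")
    }
  }

  bad <- which(fun$mean_annual_funding < 0)
  for (i in bad) v[[length(v) + 1L]] <-
    .violation("funding", i, "mean_annual_funding", "negative funding")
  dup <- which(duplicated(fun$rcdc_category))
  for (i in dup) v[[length(v) + 1L]] <-
    .violation("funding", i, "rcdc_category",
               paste0("duplicate category '", fun$rcdc_category[i], "'"))

  if (length(v) == 0L) {
    return(.violation(character(0), integer(0), character(0), character(0)))
  }
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}

# ---- file I/O --------------------------------------------------------------

.corpus_files <- c(documents = "documents.csv", mentions = "mentions.csv",
                   citations = "citations.csv", biobanks = "biobanks.csv",
                   funding = "funding.csv")

#' Write a corpus to a directory of CSV tables
#'
#' Emits `documents.csv`, `mentions.csv`, `citations.csv`, `biobanks.csv`,
#' `funding.csv` and a `corpus.yaml` holding the reference year.
#' List-valued cells are serialised with a `|` separator. Output is
#' byte-stable for identical input in identical row order.
#'
#' @param corpus a `bif_corpus`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_corpus <- function(corpus, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  docs <- corpus$documents
  flat <- data.frame(
    id = docs$id, doc_type = docs$doc_type, year = docs$year,
    author_ids = .join_list(docs$author_ids),
    affil_institutions = .join_list(docs$affil_institutions),
    affil_countries = .join_list(docs$affil_countries),
    mesh_conditions = .join_list(docs$mesh_conditions),
    mesh_categories = .join_list(docs$mesh_categories),
    rcdc_categories = .join_list(docs$rcdc_categories),
    stringsAsFactors = FALSE
  )
  bb <- corpus$biobanks
  bb_flat <- bb
  for (col in c("reference_paper_ids", "pi_ids", "team_ids"))
    bb_flat[[col]] <- .join_list(bb[[col]])
  paths <- file.path(out_dir, .corpus_files)
  names(paths) <- names(.corpus_files)
  utils::write.csv(flat, paths["documents"], row.names = FALSE)
  utils::write.csv(corpus$mentions, paths["mentions"], row.names = FALSE)
  utils::write.csv(corpus$citations, paths["citations"], row.names = FALSE)
  utils::write.csv(bb_flat, paths["biobanks"], row.names = FALSE)
  utils::write.csv(corpus$funding, paths["funding"], row.names = FALSE)
  yaml::write_yaml(list(reference_year = corpus$reference_year),
                   file.path(out_dir, "corpus.yaml"))
  invisible(c(paths, config = file.path(out_dir, "corpus.yaml")))
}

.read_documents_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  as_chr <- function(x) if (is.null(x) || length(x) == 0L) character(0) else as.character(x)
  d <- data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    doc_type = vapply(recs, function(r) as.character(r$doc_type), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    stringsAsFactors = FALSE
  )
  d$author_ids <- lapply(recs, function(r) as_chr(r$author_ids))
  d$affil_institutions <- lapply(recs, function(r)
    if (is.null(r$affiliations)) character(0) else as_chr(r$affiliations$institution))
  d$affil_countries <- lapply(recs, function(r)
    if (is.null(r$affiliations)) character(0) else as_chr(r$affiliations$country))
  d$mesh_conditions <- lapply(recs, function(r)
    if (is.null(r$mesh)) character(0) else as_chr(r$mesh$condition))
  d$mesh_categories <- lapply(recs, function(r)
    if (is.null(r$mesh)) character(0) else as_chr(r$mesh$category))
  d$rcdc_categories <- lapply(recs, function(r) as_chr(r$rcdc_categories))
  d
}

#' Load a corpus from a directory of tables
#'
#' Reads the five corpus tables (CSV; `documents.jsonl` is accepted as an
#' alternative to `documents.csv` for nested fields) plus `corpus.yaml`
#' for the reference year, collapses duplicate mention pairs with a
#' warning, and validates; any integrity violation is a fatal error naming
#' the offending table and row.
#'
#' @param dir directory containing the tables, or a list/path config with
#'   elements `documents`, `mentions`, `citations`, `biobanks`, `funding`
#'   and `reference_year` naming individual files.
#' @param reference_year overrides the configured reference year.
#' @return a validated `bif_corpus`.
#' @export
load_corpus <- function(dir, reference_year = NULL) {
  if (is.character(dir) && length(dir) == 1L && dir.exists(dir)) {
    paths <- file.path(dir, .corpus_files)
    names(paths) <- names(.corpus_files)
    jsonl <- file.path(dir, "documents.jsonl")
    if (file.exists(jsonl)) paths["documents"] <- jsonl
    cfg_path <- file.path(dir, "corpus.yaml")
    if (is.null(reference_year) && file.exists(cfg_path))
      reference_year <- yaml::read_yaml(cfg_path)$reference_year
  } else if (is.list(dir)) {
    paths <- unlist(dir[names(.corpus_files)])
    if (is.null(reference_year)) reference_year <- dir$reference_year
  } else {
    stop("corpus directory not found: ", dir)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing corpus file(s): ", paste(missing, collapse = ", "))
  if (is.null(reference_year))
    stop("reference_year not given and no corpus.yaml found")

  read_tab <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                          colClasses = "character")
  if (grepl("\\.jsonl$", paths["documents"])) {
    docs <- .read_documents_jsonl(paths["documents"])
  } else {
    docs <- read_tab(paths["documents"])
    docs$year <- as.integer(docs$year)
  }
  men <- read_tab(paths["mentions"])
  cit <- read_tab(paths["citations"])
  bb <- read_tab(paths["biobanks"])
  bb$establishment_year <- as.integer(bb$establishment_year)
  for (f in intersect(BIOBANK_FEATURES, names(bb))) bb[[f]] <- as.numeric(bb[[f]])
  fun <- read_tab(paths["funding"])
  fun$mean_annual_funding <- as.numeric(fun$mean_annual_funding)

  bif_corpus(docs, men, cit, bb, fun, reference_year, validate = TRUE)
}

# ---- shared lookups --------------------------------------------------------

# mentions restricted to documents of one type, as a data.frame with doc row
# indices attached; used throughout the analysis modules
.mentions_of_type <- function(corpus, type = "publication") {
  docs <- corpus$documents
  idx <- match(corpus$mentions$document_id, docs$id)
  keep <- docs$doc_type[idx] == type
  out <- corpus$mentions[keep, , drop = FALSE]
  out$doc_row <- idx[keep]
  out
}

# per-biobank count of distinct mentioning publications
.publication_counts <- function(corpus) {
  mp <- .mentions_of_type(corpus, "publication")
  n <- table(factor(mp$biobank_id, levels = corpus$biobanks$id))
  stats::setNames(as.integer(n), corpus$biobanks$id)
}
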