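# Biobank Impact Factor: standardized mention-based research impact R,
# three-component disease impact D, and the age-normalized combination bIF.

# z-standardize a vector across the cohort, clip to [-1, 1]; a column with
# zero spread contributes 0 for everyone
.zclip <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  pmin(1, pmax(-1, (x - mean(x)) / s))
}

#' Mention count matrix by document type
#'
#' Counts, for each eligible biobank, the number of distinct documents of
#' each of the five types that mention it.
#'
#' @param corpus a `bif_corpus`.
#' @param eligible character vector of biobank ids (rows of the result).
#' @return integer matrix, biobanks x `DOC_TYPES`.
#' @export
mention_count_matrix <- function(corpus, eligible = corpus$biobanks$id) {
  stopifnot(length(eligible) > 0L)
  men <- corpus$mentions
  men <- men[!duplicated(men[c("document_id", "biobank_id")]), , drop = FALSE]
  dt <- corpus$documents$doc_type[match(men$document_id, corpus$documents$id)]
  keep <- men$biobank_id %in% eligible
  tab <- table(factor(men$biobank_id[keep], levels = eligible),
               factor(dt[keep], levels = DOC_TYPES))
  m <- matrix(as.integer(tab), nrow = length(eligible),
              dimnames = list(eligible, DOC_TYPES))
  m
}

#' Research impact R from a mention count matrix
#'
#' Per document type, mention counts are standardized across the cohort
#' ((r - mean) / SD, sample SD) and clipped to [-1, 1] to prevent
#' document-type-specific outliers from dominating; R is the sum over the
#' five types and therefore lies in [-5, 5]. A type with zero spread
#' contributes 0.
#'
#' @param M count matrix from [mention_count_matrix()].
#' @return named numeric vector of R scores.
#' @export
research_impact <- function(M) {
  if (nrow(M) < 2L)
    stop("research impact needs >= 2 biobanks to standardize against")
  Z <- apply(M, 2, .zclip)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = nrow(M))
  r <- rowSums(Z)
  names(r) <- rownames(M)
  r
}

#' Disease impact components and D
#'
#' Three raw components per biobank, each then standardized across the
#' eligible cohort and clipped to [-1, 1] (zero-spread components give 0):
#' scope = number of distinct conditions on the biobank's mentioning
#' publications; depth = mean, over those conditions, of the biobank's
#' share of all corpus publications on the condition; rare = the biobank's
#' share of all rare-condition publications. D is their sum, in [-3, 3].
#'
#' Publications are multi-label: a publication tagged with several
#' conditions counts once toward each.
#'
#' @param corpus a `bif_corpus`.
#' @param eligible biobank ids forming the standardization cohort.
#' @param rare_condition_ids condition identifiers considered rare; if
#'   empty, the rare component is 0 for all biobanks, with a warning.
#' @return data.frame with `biobank_id`, raw components, standardized
#'   `Dscope`, `Ddepth`, `Drare`, and `D`.
#' @export
disease_impact <- function(corpus, eligible = corpus$biobanks$id,
                           rare_condition_ids = character(0)) {
  stopifnot(length(eligible) > 0L)
  docs <- corpus$documents
  mp <- .mentions_of_type(corpus, "publication")
  mp <- mp[mp$biobank_id %in% eligible, , drop = FALSE]

  # long table: (biobank, condition) pairs, one row per distinct
  # publication-condition incidence
  conds <- docs$mesh_conditions[mp$doc_row]
  nn <- lengths(conds)
  long <- data.frame(biobank_id = rep(mp$biobank_id, nn),
                     document_id = rep(mp$document_id, nn),
                     condition = unlist(conds), stringsAsFactors = FALSE)

  # corpus-wide publications per condition (all publications, not only
  # mentioning ones)
  all_pub <- docs[docs$doc_type == "publication", , drop = FALSE]
  all_long <- data.frame(
    document_id = rep(all_pub$id, lengths(all_pub$mesh_conditions)),
    condition = unlist(all_pub$mesh_conditions), stringsAsFactors = FALSE)
  all_long <- all_long[!duplicated(all_long), , drop = FALSE]
  cond_total <- table(all_long$condition)

  scope_raw <- depth_raw <- rare_raw <- stats::setNames(
    numeric(length(eligible)), eligible)

  rare_set <- unique(rare_condition_ids)
  rare_docs_all <- unique(all_long$document_id[all_long$condition %in% rare_set])
  n_rare_all <- length(rare_docs_all)
  if (length(rare_set) == 0L)
    warning("empty rare-condition set: rare component is 0 for all biobanks")

  if (nrow(long) > 0L) {
    long_u <- long[!duplicated(long), , drop = FALSE]
    by_bb <- split(long_u, long_u$biobank_id)
    for (b in names(by_bb)) {
      lb <- by_bb[[b]]
      cc <- unique(lb$condition)
      scope_raw[b] <- length(cc)
      mine <- table(factor(lb$condition, levels = cc))
      depth_raw[b] <- mean(as.numeric(mine) /
                             as.numeric(cond_total[cc]))
      if (n_rare_all > 0L) {
        my_rare <- unique(lb$document_id[lb$condition %in% rare_set])
        rare_raw[b] <- length(my_rare) / n_rare_all
      }
    }
  }

  data.frame(
    biobank_id = eligible,
    scope_raw = unname(scope_raw[eligible]),
    depth_raw = unname(depth_raw[eligible]),
    rare_raw = unname(rare_raw[eligible]),
    Dscope = .zclip(unname(scope_raw[eligible])),
    Ddepth = .zclip(unname(depth_raw[eligible])),
    Drare = .zclip(unname(rare_raw[eligible])),
    D = .zclip(unname(scope_raw[eligible])) +
      .zclip(unname(depth_raw[eligible])) +
      .zclip(unname(rare_raw[eligible])),
    stringsAsFactors = FALSE
  )
}

#' Biobank Impact Factor
#'
#' Combines research impact R and disease impact D with weights (0.9,
#' 0.1) and divides by the biobank's age in years, so a one-year-old
#' biobank at maximal R = 5 and D = 3 scores 0.9*5 + 0.1*3 = 4.8, the
#' maximum impact score; bIF always lies in [-4.8/Y, 4.8/Y]. Positive
#' values indicate above-average impact relative to the cohort.
#'
#' @param R research impact, in [-5, 5].
#' @param D disease impact, in [-3, 3].
#' @param Y age in years (>= 1).
#' @param weights length-2 weights for (R, D); alternative weights support
#'   sensitivity analysis, e.g. `c(1, 0)` ranks purely by R.
#' @return numeric bIF, vectorized over the inputs.
#' @export
compute_bif <- function(R, D, Y, weights = c(0.9, 0.1)) {
  stopifnot(length(weights) == 2L)
  if (any(Y < 1)) stop("biobank age Y must be >= 1")
  (weights[1] * R + weights[2] * D) / Y
}

#' Score and rank biobanks by Biobank Impact Factor
#'
#' Biobanks with at least `min_publications` mentioning publications form
#' the scored set and the standardization cohort for both R and D. Age is
#' `reference_year - establishment_year`, floored at 1. Result is sorted
#' by decreasing bIF, ties broken by name.
#'
#' @param corpus a `bif_corpus`.
#' @param min_publications publication-count cutoff for eligibility.
#' @param weights passed to [compute_bif()].
#' @param rare_condition_ids passed to [disease_impact()].
#' @return data.frame of class `bif_scores`: one row per scored biobank
#'   with the five per-type counts, R, the disease components, D, age `Y`
#'   and `bIF`.
#' @export
rank_biobanks <- function(corpus, min_publications = 20,
                          weights = c(0.9, 0.1),
                          rare_condition_ids = character(0)) {
  np <- .publication_counts(corpus)
  eligible <- names(np)[np >= min_publications]
  if (length(eligible) == 0L)
    stop("no biobank meets the cutoff of ", min_publications,
         " mentioning publications")
  if (length(eligible) < 2L)
    stop("only one biobank meets the cutoff; standardization needs >= 2")
  M <- mention_count_matrix(corpus, eligible)
  R <- research_impact(M)
  Dtab <- suppressWarnings(
    disease_impact(corpus, eligible, rare_condition_ids))
  bb <- corpus$biobanks
  i <- match(eligible, bb$id)
  Y <- pmax(1L, corpus$reference_year - bb$establishment_year[i])
  out <- data.frame(
    biobank_id = eligible, name = bb$name[i],
    as.data.frame(M),
    R = unname(R),
    Dscope = Dtab$Dscope, Ddepth = Dtab$Ddepth, Drare = Dtab$Drare,
    D = Dtab$D, Y = Y,
    bIF = compute_bif(unname(R), Dtab$D, Y, weights),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$bIF, out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bif_scores", "data.frame")
  out
}
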