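# Disease-category profiling and funding-representation analysis:
# principal MeSH disease category per biobank, OLS of publication output
# on category funding, and surplus/deficit residual percentages.

#' Disease-category publication counts for one biobank
#'
#' Multi-label counts of the biobank's mentioning publications per disease
#' category: a publication tagged with several categories counts once
#' toward each.
#'
#' @param corpus a `bif_corpus`.
#' @param biobank_id a biobank id.
#' @return named integer vector of per-category publication counts.
#' @export
category_counts <- function(corpus, biobank_id) {
  mp <- .mentions_of_type(corpus, "publication")
  mp <- mp[mp$biobank_id == biobank_id, , drop = FALSE]
  cats <- corpus$documents$mesh_categories[mp$doc_row]
  long <- data.frame(document_id = rep(mp$document_id, lengths(cats)),
                     category = unlist(cats), stringsAsFactors = FALSE)
  long <- long[!duplicated(long), , drop = FALSE]
  tab <- table(long$category)
  stats::setNames(as.integer(tab), names(tab))
}

#' Principal disease category of a biobank
#'
#' The disease category with the largest mentioning-publication count;
#' ties are broken lexicographically. A biobank with no disease-tagged
#' mentioning publications is labelled `"general-purpose"`.
#'
#' @inheritParams category_counts
#' @return single category name.
#' @export
principal_category <- function(corpus, biobank_id) {
  tab <- category_counts(corpus, biobank_id)
  if (length(tab) == 0L) return("general-purpose")
  nm <- names(tab)[order(-tab, names(tab))]
  nm[1]
}

#' Share of disease-tagged publications per category
#'
#' The percentage of disease-tagged publications carrying each category.
#' The denominator is the number of distinct disease-tagged publications,
#' so a category holding 15 of 100 tagged papers reports 15; because
#' tagging is multi-label, shares can sum to more than 100.
#'
#' @param corpus a `bif_corpus`.
#' @return data.frame with `category`, `n_pubs`, `share_percent`.
#' @export
category_shares <- function(corpus) {
  pub <- corpus$documents[corpus$documents$doc_type == "publication", ,
                          drop = FALSE]
  cats <- pub$mesh_categories
  tagged <- lengths(cats) > 0L
  n_tagged <- sum(tagged)
  long <- data.frame(document_id = rep(pub$id, lengths(cats)),
                     category = unlist(cats), stringsAsFactors = FALSE)
  long <- long[!duplicated(long), , drop = FALSE]
  tab <- table(long$category)
  data.frame(category = names(tab), n_pubs = as.integer(tab),
             share_percent = if (n_tagged > 0)
               100 * as.integer(tab) / n_tagged else numeric(length(tab)),
             stringsAsFactors = FALSE)
}

#' OLS fit of publication output on category funding
#'
#' Ordinary least squares of per-category publication counts on mean
#' annual funding (raw scales), with Pearson correlation and per-category
#' expected publication counts. The residuals quantify which research
#' categories are over- or underrepresented relative to their funding.
#'
#' @param funding data.frame with `rcdc_category`, `mean_annual_funding`.
#' @param actual_pubs named vector of publication counts, names matching
#'   the funding categories (missing categories count 0).
#' @return list of class `bif_funding_fit`: `slope`, `intercept`,
#'   `pearson_r`, `p_value`, and a `table` with funding, actual, expected,
#'   residual and `surplus_percent` per category.
#' @export
funding_regression <- function(funding, actual_pubs) {
  stopifnot(nrow(funding) >= 3L)
  f <- funding$mean_annual_funding
  if (stats::sd(f) == 0)
    stop("funding is constant across categories; regression is degenerate")
  a <- actual_pubs[funding$rcdc_category]
  a[is.na(a)] <- 0
  a <- as.numeric(a)
  fit <- stats::lm(a ~ f)
  expected <- unname(stats::fitted(fit))
  ct <- stats::cor.test(f, a)
  surplus <- ifelse(expected > 0, 100 * (a - expected) / expected, NA_real_)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = summary(fit)$coefficients[2, 2],
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    table = data.frame(
      rcdc_category = funding$rcdc_category,
      funding = f, actual_pubs = a, expected_pubs = expected,
      residual = a - expected, surplus_percent = surplus,
      stringsAsFactors = FALSE
    )
  ), class = "bif_funding_fit")
}

#' Per-corpus actual publication counts by RCDC category
#'
#' @param corpus a `bif_corpus`.
#' @param mentioning_only count only publications that mention a biobank.
#' @return named integer vector of counts.
#' @export
rcdc_actual_pubs <- function(corpus, mentioning_only = TRUE) {
  pub <- corpus$documents[corpus$documents$doc_type == "publication", ,
                          drop = FALSE]
  if (mentioning_only) {
    mp <- .mentions_of_type(corpus, "publication")
    pub <- pub[pub$id %in% mp$document_id, , drop = FALSE]
  }
  long <- data.frame(document_id = rep(pub$id, lengths(pub$rcdc_categories)),
                     category = unlist(pub$rcdc_categories),
                     stringsAsFactors = FALSE)
  long <- long[!duplicated(long), , drop = FALSE]
  tab <- table(long$category)
  stats::setNames(as.integer(tab), names(tab))
}

#' Representation surplus/deficit as a percentage of expectation
#'
#' `100 * (actual - expected) / expected`: positive for categories
#' overrepresented relative to their funding-predicted publication count,
#' negative for underrepresented ones. Values are returned unrounded;
#' round to the nearest integer percent for display.
#'
#' @param actual observed publication count(s).
#' @param expected regression-expected count(s), strictly positive.
#' @return numeric surplus percentage(s).
#' @export
representation_residual <- function(actual, expected) {
  if (any(expected <= 0))
    stop("expected publication count must be > 0")
  100 * (actual - expected) / expected
}
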