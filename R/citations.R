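# Citation-based impact accounting: hidden citations (mentioning papers
# that cite none of a biobank's reference papers), scientific reach
# (unique papers citing the mentioning papers), locality of mentions with
# a count-preserving permutation null, and coauthorship-for-access
# statistics.

# mentioning publications of one biobank (distinct document ids)
.mentioning_pubs <- function(corpus, biobank_id) {
  mp <- .mentions_of_type(corpus, "publication")
  unique(mp$document_id[mp$biobank_id == biobank_id])
}

#' Hidden-citation accounting for one biobank
#'
#' A hidden citation is a publication that mentions the biobank but cites
#' none of its designated reference papers: usage without citation
#' credit. Grants, patents, trials and policy documents are excluded.
#'
#' @param corpus a `bif_corpus`.
#' @param biobank_id a biobank id.
#' @return list of class `bif_hidden`: `biobank_id`, `n_mentioning`,
#'   `n_hidden`, `n_citing_reference`, `hidden_rate`, `reach`; or, for a
#'   biobank with no reference papers, the same structure with
#'   `excluded = TRUE` and `NA` rates (excluded from analysis, which is
#'   distinct from a rate of zero).
#' @export
hidden_citation_rate <- function(corpus, biobank_id) {
  bb <- corpus$biobanks
  i <- match(biobank_id, bb$id)
  if (is.na(i)) stop("unknown biobank: ", biobank_id)
  refs <- bb$reference_paper_ids[[i]]
  pubs <- .mentioning_pubs(corpus, biobank_id)
  out <- list(biobank_id = biobank_id, n_mentioning = length(pubs),
              n_hidden = NA_integer_, n_citing_reference = NA_integer_,
              hidden_rate = NA_real_,
              reach = scientific_reach(corpus, biobank_id),
              excluded = FALSE)
  if (length(refs) == 0L) {
    out$excluded <- TRUE
    class(out) <- "bif_hidden"
    return(out)
  }
  if (length(pubs) == 0L) {
    class(out) <- "bif_hidden"
    return(out)
  }
  cit <- corpus$citations
  citing_ref <- unique(cit$citing_id[cit$cited_id %in% refs])
  n_cite <- sum(pubs %in% citing_ref)
  out$n_citing_reference <- n_cite
  out$n_hidden <- length(pubs) - n_cite
  out$hidden_rate <- out$n_hidden / length(pubs)
  class(out) <- "bif_hidden"
  out
}

#' Hidden-citation table over all biobanks
#'
#' @param corpus a `bif_corpus`.
#' @return data.frame, one row per biobank with reference papers and at
#'   least one mentioning publication.
#' @export
hidden_citation_table <- function(corpus) {
  rows <- lapply(corpus$biobanks$id, function(b) {
    h <- hidden_citation_rate(corpus, b)
    if (h$excluded || h$n_mentioning == 0L) return(NULL)
    data.frame(biobank_id = h$biobank_id, n_mentioning = h$n_mentioning,
               n_hidden = h$n_hidden,
               n_citing_reference = h$n_citing_reference,
               hidden_rate = h$hidden_rate, reach = h$reach,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(biobank_id = character(0), n_mentioning = integer(0),
                      n_hidden = integer(0), n_citing_reference = integer(0),
                      hidden_rate = numeric(0), reach = integer(0))
  rownames(out) <- NULL
  out
}

#' Scientific reach of a biobank
#'
#' The number of unique documents citing at least one publication that
#' mentions the biobank — influence one citation step beyond the
#' mentioning literature.
#'
#' @inheritParams hidden_citation_rate
#' @return integer count.
#' @export
scientific_reach <- function(corpus, biobank_id) {
  pubs <- .mentioning_pubs(corpus, biobank_id)
  if (length(pubs) == 0L) return(0L)
  cit <- corpus$citations
  length(unique(cit$citing_id[cit$cited_id %in% pubs]))
}

#' Locality of a biobank's mentioning publications
#'
#' Share of mentioning publications with any author affiliation in the
#' biobank's host country (national) or at the host institution itself
#' (institutional). Denominators count mentioning publications with at
#' least one affiliation; if all affiliations are missing both shares are
#' `NA`.
#'
#' @inheritParams hidden_citation_rate
#' @return list with `national_share`, `institutional_share`, `n_pubs`
#'   (publications with affiliations).
#' @export
locality_shares <- function(corpus, biobank_id) {
  bb <- corpus$biobanks
  i <- match(biobank_id, bb$id)
  if (is.na(i)) stop("unknown biobank: ", biobank_id)
  pubs <- .mentioning_pubs(corpus, biobank_id)
  rows <- match(pubs, corpus$documents$id)
  ctry <- corpus$documents$affil_countries[rows]
  inst <- corpus$documents$affil_institutions[rows]
  has_affil <- lengths(ctry) > 0L | lengths(inst) > 0L
  if (!any(has_affil))
    return(list(national_share = NA_real_, institutional_share = NA_real_,
                n_pubs = 0L))
  nat <- vapply(ctry[has_affil], function(v) bb$host_country[i] %in% v,
                logical(1))
  ins <- vapply(inst[has_affil], function(v) bb$host_institution[i] %in% v,
                logical(1))
  list(national_share = mean(nat), institutional_share = mean(ins),
       n_pubs = sum(has_affil))
}

#' Mean locality share across biobanks
#'
#' The corpus-level statistic tested against the rewiring null: the mean,
#' over biobanks with affiliation-bearing mentioning publications, of the
#' national (or institutional) share.
#'
#' @param corpus a `bif_corpus`.
#' @param type `"national"` or `"institutional"`.
#' @param min_pubs minimum affiliation-bearing publications for a biobank
#'   to enter the mean.
#' @return scalar mean share.
#' @export
mean_locality_share <- function(corpus, type = c("national", "institutional"),
                                min_pubs = 1L) {
  type <- match.arg(type)
  sh <- vapply(corpus$biobanks$id, function(b) {
    l <- locality_shares(corpus, b)
    if (l$n_pubs < min_pubs) return(NA_real_)
    if (type == "national") l$national_share else l$institutional_share
  }, numeric(1))
  mean(sh, na.rm = TRUE)
}

#' Permutation null test for locality (count-preserving rewiring)
#'
#' Randomly reassigns biobank labels over the mention slots — a
#' permutation of the mention table's biobank column — which preserves
#' each biobank's mention count and each document's number of mention
#' slots exactly, i.e. a degree-preserving rewiring of the bipartite
#' document-biobank mention graph. The observed statistic is compared to
#' its null distribution with the add-one-corrected empirical p-value
#' `(1 + #[null >= obs]) / (1 + n_iter)`.
#'
#' @param corpus a `bif_corpus`.
#' @param statistic function `corpus -> scalar`; default is the mean
#'   national locality share ([mean_locality_share()]).
#' @param n_iter number of permutations (>= 1).
#' @param seed integer seed; the null distribution is reproducible.
#' @return list of class `bif_null_test`: `observed`, `null` (length
#'   `n_iter`), `p_value`, `n_iter`.
#' @export
rewiring_null_test <- function(corpus, statistic = mean_locality_share,
                               n_iter = 1000L, seed = 7L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (nrow(corpus$biobanks) < 2L) stop("need >= 2 biobanks")
  observed <- statistic(corpus)
  base_counts <- table(corpus$mentions$biobank_id)
  null <- .with_seed(seed, vapply(seq_len(n_iter), function(it) {
    perm <- corpus$mentions
    perm$biobank_id <- sample(perm$biobank_id)
    # rewiring invariant: per-biobank mention counts are preserved exactly
    stopifnot(identical(table(perm$biobank_id), base_counts))
    cp <- corpus
    cp$mentions <- perm
    statistic(cp)
  }, numeric(1)))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_iter),
                 n_iter = n_iter),
            class = "bif_null_test")
}

#' Coauthorship-for-access statistics for one biobank
#'
#' Shares of the biobank's mentioning publications listing at least one
#' team member, at least one PI, and a non-PI team member without any PI
#' — the signature of access granted in exchange for coauthorship.
#'
#' @inheritParams hidden_citation_rate
#' @return list of class `bif_coauth`: `team_share`, `pi_share`,
#'   `non_pi_without_pi_count`, `non_pi_without_pi_share`,
#'   `n_mentioning`; all-`NA` with `undefined = TRUE` if the team roster
#'   is empty.
#' @export
coauthorship_stats <- function(corpus, biobank_id) {
  bb <- corpus$biobanks
  i <- match(biobank_id, bb$id)
  if (is.na(i)) stop("unknown biobank: ", biobank_id)
  team <- bb$team_ids[[i]]
  pis <- bb$pi_ids[[i]]
  pubs <- .mentioning_pubs(corpus, biobank_id)
  if (length(team) == 0L || length(pubs) == 0L) {
    return(structure(list(biobank_id = biobank_id, team_share = NA_real_,
                          pi_share = NA_real_,
                          non_pi_without_pi_count = NA_integer_,
                          non_pi_without_pi_share = NA_real_,
                          n_mentioning = length(pubs), undefined = TRUE),
                     class = "bif_coauth"))
  }
  auth <- corpus$documents$author_ids[match(pubs, corpus$documents$id)]
  has_team <- vapply(auth, function(a) any(a %in% team), logical(1))
  has_pi <- vapply(auth, function(a) any(a %in% pis), logical(1))
  npwp <- has_team & !has_pi
  structure(list(biobank_id = biobank_id,
                 team_share = mean(has_team), pi_share = mean(has_pi),
                 non_pi_without_pi_count = sum(npwp),
                 non_pi_without_pi_share = mean(npwp),
                 n_mentioning = length(pubs), undefined = FALSE),
            class = "bif_coauth")
}

#' Compare a metric between top and bottom bIF quintiles
#'
#' Splits scored biobanks into bottom-20% and top-20% by bIF and compares
#' the supplied per-biobank metric with group means, 95% confidence
#' intervals and a Welch two-sample t-test.
#'
#' @param scores a `bif_scores` table from [rank_biobanks()].
#' @param metric named numeric vector (names = biobank ids).
#' @return list of class `bif_quintile`: per-group `n`, `mean`, `ci`
#'   (95%), plus `difference` and `p_value`.
#' @export
quintile_compare <- function(scores, metric) {
  stopifnot(nrow(scores) >= 5L)
  k <- floor(nrow(scores) / 5)
  ord <- order(scores$bIF, decreasing = TRUE)
  top_ids <- scores$biobank_id[ord[seq_len(k)]]
  bot_ids <- scores$biobank_id[ord[seq(nrow(scores) - k + 1, nrow(scores))]]
  top <- metric[top_ids]; bot <- metric[bot_ids]
  top <- top[is.finite(top)]; bot <- bot[is.finite(bot)]
  if (length(top) < 2L || length(bot) < 2L)
    stop("fewer than 2 biobanks with finite metric per quintile")
  ci <- function(x) {
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    m + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
  }
  if (stats::sd(top) == 0 && stats::sd(bot) == 0) {
    p <- if (isTRUE(all.equal(mean(top), mean(bot)))) 1 else 0
  } else {
    p <- stats::t.test(top, bot)$p.value
  }
  structure(list(
    n_per_group = k,
    top = list(n = length(top), mean = mean(top), ci = ci(top)),
    bottom = list(n = length(bot), mean = mean(bot), ci = ci(bot)),
    difference = mean(top) - mean(bot), p_value = p),
    class = "bif_quintile")
}
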