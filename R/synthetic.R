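# Synthetic corpus generation with planted, recoverable parameters.
#
# The generator emulates the statistical structure the analyses assume:
# heavy-tailed per-biobank mention counts across five document types,
# host-country home bias in author affiliations, a bimodal distribution of
# team-coauthorship rates, a tunable hidden-citation rate, Dirichlet
# disease-category profiles, and funding-proportional publication volumes.

#' Configuration for the synthetic corpus generator
#'
#' Defaults are chosen to echo the empirical regime of large biobank
#' mention corpora: a log-normal per-biobank mention intensity, a document
#' type mix dominated by publications, a hidden-citation rate of 0.412, a
#' national home bias of 0.735 with institutional bias 0.294, and a
#' bimodal team-coauthorship mixture with mean share near 0.6.
#'
#' @param n_biobanks number of biobanks (>= 2).
#' @param mention_meanlog,mention_sdlog location and scale of the
#'   log-normal law for a biobank's total mention intensity.
#' @param doc_type_mix proportions of mentions over the five document
#'   types, in [DOC_TYPES] order.
#' @param hidden_citation_rate probability that a mentioning publication
#'   fails to cite any reference paper of the biobank.
#' @param home_bias probability that a mentioning publication's lead
#'   affiliation is in the biobank's host country.
#' @param institution_bias probability that it is the host institution
#'   itself (must not exceed `home_bias`).
#' @param team_coauthor_mixture two-component mixture over per-biobank
#'   team-coauthorship probability: list with `weights`, `means`, `sd`.
#' @param n_disease_categories number of disease categories.
#' @param category_concentration Dirichlet concentration of per-biobank
#'   category profiles (small = focused biobanks).
#' @param conditions_per_category conditions within each category; the
#'   last `ceiling(rare_fraction * conditions_per_category)` of each
#'   category form the rare-disease set.
#' @param rare_fraction fraction of conditions flagged rare.
#' @param funding_per_category named USD vector of mean annual funding by
#'   RCDC category.
#' @param pubs_per_funding_slope expected publications per USD of category
#'   funding.
#' @param noise_sd SD (in publications) of per-category count noise.
#' @param citer_rate background third-party citing papers per mentioning
#'   publication.
#' @param n_countries size of the country pool.
#' @param team_size,n_pis team roster size and number of PIs per biobank.
#' @param establishment_year_range,reference_year year bounds.
#'
#' @return a validated list of class `bif_generator_config`.
#' @export
generator_config <- function(n_biobanks = 50,
                             mention_meanlog = log(60),
                             mention_sdlog = 1,
                             doc_type_mix = c(publication = 0.8422,
                                              grant = 0.0597,
                                              patent = 0.0569,
                                              clinical_trial = 0.0065,
                                              policy = 0.0347),
                             hidden_citation_rate = 0.412,
                             home_bias = 0.735,
                             institution_bias = 0.294,
                             team_coauthor_mixture = list(
                               weights = c(0.4, 0.6),
                               means = c(0.05, 0.95),
                               sd = 0.02),
                             n_disease_categories = 20,
                             category_concentration = 0.3,
                             conditions_per_category = 10,
                             rare_fraction = 0.1,
                             funding_per_category = NULL,
                             pubs_per_funding_slope = 2.5e-8,
                             noise_sd = 10,
                             citer_rate = 0.8,
                             n_countries = 20,
                             team_size = 8,
                             n_pis = 2,
                             establishment_year_range = c(1990, 2015),
                             reference_year = 2024) {
  if (is.null(funding_per_category)) {
    funding_per_category <- stats::setNames(
      seq(0.5e9, 12.8e9, length.out = 20),
      sprintf("RCDC_%02d", 1:20))
  }
  cfg <- list(
    n_biobanks = as.integer(n_biobanks),
    mention_meanlog = mention_meanlog, mention_sdlog = mention_sdlog,
    doc_type_mix = doc_type_mix,
    hidden_citation_rate = hidden_citation_rate,
    home_bias = home_bias, institution_bias = institution_bias,
    team_coauthor_mixture = team_coauthor_mixture,
    n_disease_categories = as.integer(n_disease_categories),
    category_concentration = category_concentration,
    conditions_per_category = as.integer(conditions_per_category),
    rare_fraction = rare_fraction,
    funding_per_category = funding_per_category,
    pubs_per_funding_slope = pubs_per_funding_slope,
    noise_sd = noise_sd, citer_rate = citer_rate,
    n_countries = as.integer(n_countries),
    team_size = as.integer(team_size), n_pis = as.integer(n_pis),
    establishment_year_range = as.integer(establishment_year_range),
    reference_year = as.integer(reference_year)
  )
  class(cfg) <- "bif_generator_config"
  .check_generator_config(cfg)
  cfg
}

.check_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_biobanks >= 2L,
    cfg$hidden_citation_rate >= 0, cfg$hidden_citation_rate <= 1,
    cfg$home_bias >= 0, cfg$home_bias <= 1,
    cfg$institution_bias >= 0, cfg$institution_bias <= cfg$home_bias,
    all(cfg$doc_type_mix >= 0),
    length(cfg$doc_type_mix) == 5L,
    abs(sum(cfg$team_coauthor_mixture$weights) - 1) < 1e-8,
    all(cfg$team_coauthor_mixture$means >= 0),
    all(cfg$team_coauthor_mixture$means <= 1),
    all(cfg$funding_per_category >= 0),
    cfg$n_disease_categories >= 1L,
    cfg$mention_sdlog >= 0,
    sum(cfg$doc_type_mix) > 0
  )
  invisible(cfg)
}

# run expr with an isolated, seeded RNG stream; global .Random.seed restored
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Produces a corpus that passes [validate_corpus()] together with a truth
#' record of every planted parameter, so downstream estimators can be
#' checked for recovery. Each mentioning publication cites one of its
#' biobank's reference papers with probability `1 - hidden_citation_rate`;
#' its lead affiliation is the host institution with probability
#' `institution_bias`, elsewhere in the host country with probability
#' `home_bias - institution_bias`, and foreign otherwise; a team member is
#' a coauthor with the biobank's planted coauthorship probability (a PI
#' half of those times). Per-RCDC-category publication tags are
#' `max(0, round(slope * funding + noise))`, so an OLS fit of tag counts
#' on funding recovers the planted slope. Background citing papers make
#' reach and cocitation non-degenerate.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; identical seeds give identical corpora. The
#'   global RNG state is left untouched.
#' @return list with elements `corpus` (a `bif_corpus`) and `truth` (the
#'   planted-parameter record: `params`, per-biobank `biobanks` table, and
#'   the per-category `rcdc` table with planted counts).
#' @export
generate_corpus <- function(cfg = generator_config(), seed = 1L) {
  .check_generator_config(cfg)
  .with_seed(seed, .generate_corpus_impl(cfg, seed))
}

.generate_corpus_impl <- function(cfg, seed) {
  nb <- cfg$n_biobanks
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  cats <- sprintf("CAT%02d", seq_len(cfg$n_disease_categories))
  mix <- cfg$doc_type_mix / sum(cfg$doc_type_mix)

  # --- biobank-level draws --------------------------------------------------
  bb_id <- sprintf("BB%03d", seq_len(nb))
  est <- sample(seq(cfg$establishment_year_range[1],
                    cfg$establishment_year_range[2]), nb, replace = TRUE)
  host_country <- sample(countries, nb, replace = TRUE)
  host_inst <- paste0("INST_", bb_id)
  team <- lapply(bb_id, function(b) paste0(b, "_T", seq_len(cfg$team_size)))
  pis <- lapply(team, function(t) t[seq_len(cfg$n_pis)])

  mx <- cfg$team_coauthor_mixture
  comp <- sample(seq_along(mx$weights), nb, replace = TRUE, prob = mx$weights)
  coauth_p <- pmin(1, pmax(0, stats::rnorm(nb, mx$means[comp], mx$sd)))

  intensity <- stats::rlnorm(nb, cfg$mention_meanlog, cfg$mention_sdlog)
  n_mentions <- stats::rpois(nb, intensity)

  # Dirichlet category profiles (small concentration -> focused biobanks)
  prof <- matrix(stats::rgamma(nb * length(cats),
                               shape = cfg$category_concentration),
                 nrow = nb)
  prof <- prof / pmax(rowSums(prof), .Machine$double.eps)
  planted_cat <- cats[max.col(prof, ties.method = "first")]

  features <- data.frame(
    sample_size_large = stats::rbinom(nb, 1, 0.1),
    open_data_index = sample(0:2, nb, replace = TRUE),
    pi_prestige = stats::rbinom(nb, 1, 0.1),
    population_based = stats::rbinom(nb, 1, 0.5),
    genetic_markers = stats::rbinom(nb, 1, 0.5),
    gwas = stats::rbinom(nb, 1, 0.4),
    whole_genome_seq = stats::rbinom(nb, 1, 0.3),
    gene_environment = stats::rbinom(nb, 1, 0.3),
    registries = stats::rbinom(nb, 1, 0.4),
    surveys = stats::rbinom(nb, 1, 0.5),
    follow_up = stats::rbinom(nb, 1, 0.5),
    medical_records = stats::rbinom(nb, 1, 0.5),
    hospital_based = stats::rbinom(nb, 1, 0.3),
    general_purpose = stats::rbinom(nb, 1, 0.2)
  )

  # --- reference papers -----------------------------------------------------
  n_refs <- sample(1:3, nb, replace = TRUE)
  ref_ids <- lapply(seq_len(nb), function(b)
    sprintf("%s_REF%d", bb_id[b], seq_len(n_refs[b])))
  ref_docs <- data.frame(
    id = unlist(ref_ids),
    doc_type = "publication",
    year = rep(pmin(est + 1L, cfg$reference_year), n_refs),
    stringsAsFactors = FALSE
  )
  ref_owner <- rep(seq_len(nb), n_refs)
  ref_docs$author_ids <- pis[ref_owner]
  ref_docs$affil_institutions <- as.list(host_inst[ref_owner])
  ref_docs$affil_countries <- as.list(host_country[ref_owner])
  ref_docs$mesh_conditions <- replicate(nrow(ref_docs), character(0),
                                        simplify = FALSE)
  ref_docs$mesh_categories <- replicate(nrow(ref_docs), character(0),
                                        simplify = FALSE)
  ref_docs$rcdc_categories <- replicate(nrow(ref_docs), character(0),
                                        simplify = FALSE)

  # --- mentioning documents -------------------------------------------------
  owner <- rep(seq_len(nb), n_mentions)
  n_docs <- length(owner)
  if (n_docs == 0L)
    stop("degenerate configuration: zero mentioning documents generated")
  doc_type <- DOC_TYPES[apply(stats::rmultinom(n_docs, 1, mix), 2, which.max)]
  doc_id <- sprintf("D%06d", seq_len(n_docs))
  year <- est[owner] +
    floor(stats::runif(n_docs) * pmax(1, cfg$reference_year - est[owner])) + 1L
  year <- pmin(year, cfg$reference_year)

  is_pub <- doc_type == "publication"
  n_pub <- sum(is_pub)

  # authorship: two external authors, plus a team member with the planted
  # per-biobank coauthorship probability (a PI for half of those events)
  author_ids <- replicate(n_docs, character(0), simplify = FALSE)
  affil_inst <- replicate(n_docs, character(0), simplify = FALSE)
  affil_ctry <- replicate(n_docs, character(0), simplify = FALSE)
  if (n_pub > 0L) {
    pub_idx <- which(is_pub)
    ob <- owner[pub_idx]
    ext1 <- sprintf("EXT%07d", sample.int(9999999L, n_pub, replace = TRUE))
    ext2 <- sprintf("EXT%07d", sample.int(9999999L, n_pub, replace = TRUE))
    team_event <- stats::runif(n_pub) < coauth_p[ob]
    pi_event <- team_event & (stats::runif(n_pub) < 0.5)
    team_author <- character(n_pub)
    for (j in which(team_event)) {
      pool <- if (pi_event[j]) pis[[ob[j]]] else
        setdiff(team[[ob[j]]], pis[[ob[j]]])
      team_author[j] <- pool[sample.int(length(pool), 1L)]
    }
    # lead affiliation decides locality; extra affiliations stay foreign
    u <- stats::runif(n_pub)
    inst_match <- u < cfg$institution_bias
    ctry_match <- u < cfg$home_bias
    lead_ctry <- character(n_pub)
    lead_inst <- character(n_pub)
    lead_ctry[ctry_match] <- host_country[ob[ctry_match]]
    lead_inst[inst_match] <- host_inst[ob[inst_match]]
    nat_only <- ctry_match & !inst_match
    lead_inst[nat_only] <- paste0("INST_", lead_ctry[nat_only], "_",
                                  sample.int(5L, sum(nat_only), replace = TRUE))
    for (j in which(!ctry_match)) {
      lead_ctry[j] <- sample(setdiff(countries, host_country[ob[j]]), 1L)
    }
    lead_inst[!ctry_match] <- paste0("INST_", lead_ctry[!ctry_match], "_",
                                     sample.int(5L, sum(!ctry_match),
                                                replace = TRUE))
    for (k in seq_len(n_pub)) {
      i <- pub_idx[k]
      auth <- c(ext1[k], ext2[k])
      if (team_event[k]) auth <- c(auth, team_author[k])
      author_ids[[i]] <- auth
      affil_inst[[i]] <- lead_inst[k]
      affil_ctry[[i]] <- lead_ctry[k]
    }
  }

  # MeSH condition tags from the biobank's Dirichlet category profile
  mesh_cond <- replicate(n_docs, character(0), simplify = FALSE)
  mesh_cat <- replicate(n_docs, character(0), simplify = FALSE)
  if (n_pub > 0L) {
    pub_idx <- which(is_pub)
    n_tags <- 1L + stats::rpois(n_pub, 0.8)
    for (k in seq_len(n_pub)) {
      b <- owner[pub_idx[k]]
      cc <- sample(cats, n_tags[k], replace = TRUE, prob = prof[b, ])
      jj <- sample.int(cfg$conditions_per_category, n_tags[k], replace = TRUE)
      cond <- sprintf("%s_COND%02d", cc, jj)
      keep <- !duplicated(cond)
      mesh_cond[[pub_idx[k]]] <- cond[keep]
      mesh_cat[[pub_idx[k]]] <- cc[keep]
    }
  }

  # RCDC tags: per-category counts linear in funding, planted slope
  rcdc <- replicate(n_docs, character(0), simplify = FALSE)
  fcat <- names(cfg$funding_per_category)
  planted_n <- pmax(0, round(cfg$pubs_per_funding_slope *
                               cfg$funding_per_category +
                               stats::rnorm(length(fcat), 0, cfg$noise_sd)))
  if (n_pub > 0L) {
    pub_idx <- which(is_pub)
    planted_n <- pmin(planted_n, n_pub)
    for (ci in seq_along(fcat)) {
      if (planted_n[ci] == 0) next
      chosen <- pub_idx[sample.int(n_pub, planted_n[ci])]
      for (i in chosen) rcdc[[i]] <- c(rcdc[[i]], fcat[ci])
    }
  }

  ment_docs <- data.frame(id = doc_id, doc_type = doc_type, year = year,
                          stringsAsFactors = FALSE)
  ment_docs$author_ids <- author_ids
  ment_docs$affil_institutions <- affil_inst
  ment_docs$affil_countries <- affil_ctry
  ment_docs$mesh_conditions <- mesh_cond
  ment_docs$mesh_categories <- mesh_cat
  ment_docs$rcdc_categories <- rcdc

  mentions <- data.frame(
    document_id = doc_id, biobank_id = bb_id[owner],
    location = sample(c("title", "abstract", "acknowledgments"), n_docs,
                      replace = TRUE, prob = c(0.2, 0.6, 0.2)),
    stringsAsFactors = FALSE
  )

  # --- citations ------------------------------------------------------------
  # mentioning publications cite a reference paper unless hidden
  cit <- list()
  if (n_pub > 0L) {
    pub_idx <- which(is_pub)
    cites_ref <- stats::runif(n_pub) >= cfg$hidden_citation_rate
    tgt <- vapply(owner[pub_idx], function(b)
      ref_ids[[b]][sample.int(length(ref_ids[[b]]), 1L)], character(1))
    cit[[1L]] <- data.frame(citing_id = doc_id[pub_idx][cites_ref],
                            cited_id = tgt[cites_ref],
                            stringsAsFactors = FALSE)
  }

  # background third-party citers: each picks a focal disease category and
  # preferentially cites publications of biobanks focused on it, giving the
  # cocitation network a community structure aligned with disease categories
  n_citers <- round(cfg$citer_rate * n_pub)
  citer_docs <- NULL
  if (n_citers > 0L && n_pub > 0L) {
    pub_idx <- which(is_pub)
    citer_id <- sprintf("CITER%06d", seq_len(n_citers))
    citer_docs <- data.frame(
      id = citer_id, doc_type = "publication",
      year = sample(seq(cfg$establishment_year_range[1] + 1L,
                        cfg$reference_year), n_citers, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (col in c("author_ids", "affil_institutions", "affil_countries",
                  "mesh_conditions", "mesh_categories", "rcdc_categories"))
      citer_docs[[col]] <- replicate(n_citers, character(0), simplify = FALSE)
    pub_cat <- planted_cat[owner[pub_idx]]
    by_cat <- split(seq_len(n_pub), pub_cat)
    focal <- sample(cats, n_citers, replace = TRUE)
    k_cited <- 1L + stats::rpois(n_citers, 1.5)
    edges <- vector("list", n_citers)
    for (m in seq_len(n_citers)) {
      pool <- by_cat[[focal[m]]]
      k <- k_cited[m]
      if (!is.null(pool) && length(pool) > 0L && stats::runif(1) < 0.7) {
        pick <- pool[sample.int(length(pool), min(k, length(pool)))]
      } else {
        pick <- sample.int(n_pub, min(k, n_pub))
      }
      edges[[m]] <- data.frame(citing_id = citer_id[m],
                               cited_id = doc_id[pub_idx][pick],
                               stringsAsFactors = FALSE)
    }
    cit[[length(cit) + 1L]] <- do.call(rbind, edges)
  }
  citations <- if (length(cit) > 0L) do.call(rbind, cit) else
    data.frame(citing_id = character(0), cited_id = character(0))
  citations <- citations[!duplicated(citations), , drop = FALSE]
  rownames(citations) <- NULL

  documents <- rbind(ref_docs, ment_docs,
                     if (!is.null(citer_docs)) citer_docs)
  rownames(documents) <- NULL

  biobanks <- data.frame(
    id = bb_id, name = paste0("Biobank ", bb_id),
    establishment_year = est, host_institution = host_inst,
    host_country = host_country, stringsAsFactors = FALSE
  )
  biobanks$reference_paper_ids <- ref_ids
  biobanks$pi_ids <- pis
  biobanks$team_ids <- team
  biobanks <- cbind(biobanks, features)

  funding <- data.frame(rcdc_category = fcat,
                        mean_annual_funding = unname(cfg$funding_per_category),
                        stringsAsFactors = FALSE)

  corpus <- bif_corpus(documents, mentions, citations, biobanks, funding,
                       cfg$reference_year, validate = FALSE)

  truth <- list(
    seed = seed,
    params = list(hidden_citation_rate = cfg$hidden_citation_rate,
                  home_bias = cfg$home_bias,
                  institution_bias = cfg$institution_bias,
                  pubs_per_funding_slope = cfg$pubs_per_funding_slope),
    biobanks = data.frame(
      id = bb_id, intensity = intensity, n_mentions = n_mentions,
      coauthor_prob = coauth_p, coauthor_component = comp,
      principal_category = planted_cat, stringsAsFactors = FALSE
    ),
    rcdc = data.frame(rcdc_category = fcat,
                      mean_annual_funding = unname(cfg$funding_per_category),
                      planted_count = unname(planted_n),
                      stringsAsFactors = FALSE)
  )
  list(corpus = corpus, truth = truth)
}

#' Simulate a biobank feature study with planted coefficients
#'
#' Draws a binary 14-feature design (the two top-decile flags at
#' probability 0.1, the rest at 0.5) and a response generated from the
#' feature-regression model: `log(bIF + 1) = b0 + X b + e`,
#' `e ~ N(0, noise_sd)`. Used to check coefficient recovery, confidence
#' interval coverage and the Bonferroni type-I error rate of
#' [fit_feature_model()].
#'
#' @param n number of biobanks.
#' @param beta planted coefficient vector of length 15 (intercept first);
#'   default all zero.
#' @param noise_sd residual SD on the log scale.
#' @param seed integer seed.
#' @return list with `features` (data.frame of the 14 columns), `bif`
#'   (response on the original scale), and `beta`.
#' @export
simulate_feature_study <- function(n = 500, beta = rep(0, 15),
                                   noise_sd = 0.05, seed = 1L) {
  stopifnot(length(beta) == 15L, n >= 2)
  .with_seed(seed, {
    p_on <- ifelse(BIOBANK_FEATURES %in% c("sample_size_large", "pi_prestige"),
                   0.1, 0.5)
    X <- vapply(p_on, function(p) stats::rbinom(n, 1, p), numeric(n))
    colnames(X) <- BIOBANK_FEATURES
    eta <- beta[1] + drop(X %*% beta[-1]) + stats::rnorm(n, 0, noise_sd)
    list(features = as.data.frame(X), bif = exp(eta) - 1, beta = beta)
  })
}
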