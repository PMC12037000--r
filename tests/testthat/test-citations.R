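test_that("hidden-citation counts partition the mentioning publications", {
  cp <- tiny_corpus()
  # B1: mentioning pubs P3 (cites P1, its reference) and P4 (does not)
  h <- hidden_citation_rate(cp, "B1")
  expect_equal(h$n_mentioning, 2L)
  expect_equal(h$n_hidden, 1L)
  expect_equal(h$n_citing_reference, 1L)
  expect_equal(h$hidden_rate, 0.5)
  expect_equal(h$n_hidden + h$n_citing_reference, h$n_mentioning)
  # B2: its only mentioning pub P5 cites its reference P2 -> rate 0
  expect_equal(hidden_citation_rate(cp, "B2")$hidden_rate, 0)
})

test_that("a 10-paper fixture with 4 uncited-reference papers gives rate 0.4", {
  cp0 <- tiny_corpus()
  n <- 10
  docs <- cp0$documents[rep(3, n), ]
  docs$id <- sprintf("M%02d", 1:n)
  for (col in c("mesh_conditions", "mesh_categories", "rcdc_categories"))
    docs[[col]] <- replicate(n, character(0), simplify = FALSE)
  docs <- rbind(cp0$documents[1:2, ], docs)
  men <- data.frame(document_id = sprintf("M%02d", 1:n), biobank_id = "B1",
                    location = "abstract")
  # 6 of 10 cite the reference paper P1
  cit <- data.frame(citing_id = sprintf("M%02d", 1:6), cited_id = "P1")
  cp <- bif_corpus(docs, men, cit, cp0$biobanks, cp0$funding, 2024)
  h <- hidden_citation_rate(cp, "B1")
  expect_equal(h$hidden_rate, 0.4)

  # all-hidden and all-citing extremes
  cp_all <- bif_corpus(docs, men, cit[0, ], cp0$biobanks, cp0$funding, 2024)
  expect_equal(hidden_citation_rate(cp_all, "B1")$hidden_rate, 1)
  cit_full <- data.frame(citing_id = sprintf("M%02d", 1:n), cited_id = "P1")
  cp_none <- bif_corpus(docs, men, cit_full, cp0$biobanks, cp0$funding, 2024)
  expect_equal(hidden_citation_rate(cp_none, "B1")$hidden_rate, 0)
})

test_that("a biobank without reference papers is excluded, not zero", {
  cp <- tiny_corpus()
  cp$biobanks$reference_paper_ids[[1]] <- character(0)
  h <- hidden_citation_rate(cp, "B1")
  expect_true(h$excluded)
  expect_true(is.na(h$hidden_rate))
  expect_false("B1" %in% hidden_citation_table(cp)$biobank_id)
})

test_that("scientific reach deduplicates citing articles and matches set-union enumeration", {
  cp <- tiny_corpus()
  # B2's mentioning pub P5 is cited by P4 only
  expect_equal(scientific_reach(cp, "B2"), 1L)
  # no one cites B1's mentioning pubs
  expect_equal(scientific_reach(cp, "B1"), 0L)

  # two mentioning papers cited by the same third paper count once
  docs <- cp$documents
  cit <- rbind(cp$citations, data.frame(citing_id = c("G1", "G1"),
                                        cited_id = c("P3", "P4")))
  cp2 <- bif_corpus(docs, cp$mentions, cit, cp$biobanks, cp$funding, 2024)
  expect_equal(scientific_reach(cp2, "B1"), 1L)

  for (s in 21:23) {
    cpr <- random_fixture(s)$corpus
    for (b in cpr$biobanks$id)
      expect_equal(scientific_reach(cpr, b), oracle_reach(cpr, b))
  }
})

test_that("reach is at least any single paper's distinct citer count", {
  cp <- random_fixture(24)$corpus
  for (b in cp$biobanks$id[1:5]) {
    pubs <- oracle_mentioning_pubs(cp, b)
    if (length(pubs) == 0) next
    per_pub <- vapply(pubs, function(p)
      length(unique(cp$citations$citing_id[cp$citations$cited_id == p])),
      numeric(1))
    expect_gte(scientific_reach(cp, b), max(per_pub))
  }
})

test_that("locality shares use any-author matching over affiliation-bearing pubs", {
  cp <- tiny_corpus()
  # B1: P3 affiliated INST_A/AA (host), P4 INST_C/BB -> (0.5, 0.5)
  l <- locality_shares(cp, "B1")
  expect_equal(l$national_share, 0.5)
  expect_equal(l$institutional_share, 0.5)
  # B2: P5 at host INST_B/BB -> (1, 1)
  l2 <- locality_shares(cp, "B2")
  expect_equal(l2$national_share, 1)
  expect_equal(l2$institutional_share, 1)

  # no paper from the host country -> (0, 0)
  cp2 <- cp
  cp2$biobanks$host_country[1] <- "ZZ"
  cp2$biobanks$host_institution[1] <- "INST_Z"
  l3 <- locality_shares(cp2, "B1")
  expect_equal(l3$national_share, 0)
  expect_equal(l3$institutional_share, 0)

  # all affiliations missing -> undefined
  cp3 <- cp
  cp3$documents$affil_countries[3:4] <- list(character(0), character(0))
  cp3$documents$affil_institutions[3:4] <- list(character(0), character(0))
  expect_true(is.na(locality_shares(cp3, "B1")$national_share))
})

test_that("rewiring null is deterministic, count-preserving and bounded", {
  cp <- random_fixture(31)$corpus
  nt1 <- rewiring_null_test(cp, n_iter = 50, seed = 9)
  nt2 <- rewiring_null_test(cp, n_iter = 50, seed = 9)
  expect_identical(nt1$null, nt2$null)
  expect_gte(nt1$p_value, 1 / 51)
  expect_lte(nt1$p_value, 1)
  expect_error(rewiring_null_test(cp, n_iter = 0), "n_iter")
})

test_that("coauthorship shares scan rosters correctly", {
  cp <- tiny_corpus()
  # B1: P3 has team member t1 (not PI), P4 has none
  s <- coauthorship_stats(cp, "B1")
  expect_equal(s$team_share, 0.5)
  expect_equal(s$pi_share, 0)
  expect_equal(s$non_pi_without_pi_count, 1L)
  # B2: P5 lists PI p2
  s2 <- coauthorship_stats(cp, "B2")
  expect_equal(s2$pi_share, 1)
  expect_equal(s2$team_share, 1)
  expect_equal(s2$non_pi_without_pi_count, 0L)
  expect_lte(s2$pi_share, s2$team_share)

  # no roster overlap -> all zero
  cp2 <- cp
  cp2$biobanks$pi_ids[[1]] <- "q1"
  cp2$biobanks$team_ids[[1]] <- c("q1", "q2")
  s3 <- coauthorship_stats(cp2, "B1")
  expect_equal(s3$team_share, 0)
  expect_equal(s3$pi_share, 0)

  # empty roster is an undefined signal
  cp3 <- cp
  cp3$biobanks$pi_ids[[1]] <- character(0)
  cp3$biobanks$team_ids[[1]] <- character(0)
  expect_true(coauthorship_stats(cp3, "B1")$undefined)

  for (s in 41:43) {
    cpr <- random_fixture(s)$corpus
    for (b in cpr$biobanks$id) {
      o <- oracle_coauth_shares(cpr, b)
      if (is.null(o)) next
      st <- coauthorship_stats(cpr, b)
      expect_equal(st$team_share, unname(o["team"]))
      expect_equal(st$pi_share, unname(o["pi"]))
      expect_lte(st$pi_share, st$team_share)
    }
  }
})

test_that("quintile comparison splits 20% per group and detects planted separation", {
  fake_scores <- function(n, bif) {
    structure(data.frame(biobank_id = sprintf("B%03d", 1:n), bIF = bif,
                         stringsAsFactors = FALSE),
              class = c("bif_scores", "data.frame"))
  }
  sc <- fake_scores(100, seq(1, 0, length.out = 100))
  metric <- stats::setNames(rep(5, 100), sc$biobank_id)
  q <- quintile_compare(sc, metric)
  expect_equal(q$n_per_group, 20L)
  expect_equal(q$difference, 0)
  expect_gte(q$p_value, 0.99)

  # two planted groups 3 SD apart, n = 50 per group
  set.seed(77)
  sc2 <- fake_scores(250, seq(1, 0, length.out = 250))
  metric2 <- stats::setNames(
    c(rnorm(50, 3, 1), rnorm(150, 1.5, 1), rnorm(50, 0, 1)),
    sc2$biobank_id)
  q2 <- quintile_compare(sc2, metric2)
  expect_equal(q2$n_per_group, 50L)
  expect_lt(q2$p_value, 0.001)
  expect_gt(q2$difference, 2)
  # CIs are ordered around the means
  expect_lt(q2$top$ci[1], q2$top$mean)
  expect_gt(q2$top$ci[2], q2$top$mean)

  expect_error(quintile_compare(sc[1:4, ], metric[1:4]))
})
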