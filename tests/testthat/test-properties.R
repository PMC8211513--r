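# Property-style checks of the scoring algebra on randomly generated
# small corpora.

test_that("joint-form and ratio-form scores agree on cooccurring pairs", {
  # P(d|X) = [prod P(s|d)] P(d) / [prod P(s)]  vs
  #          [prod P(s|d)/P(s)] P(d)
  set.seed(101)
  for (rep in 1:20) {
    recs <- random_corpus(sample(2:4, 1), sample(3:6, 1), 25L)
    m <- nb_fit(recs)
    cfg <- nb_variant("empirical", "product")
    for (d in m$diseases) {
      full <- m$symptoms[m$pair_counts[d, ] > 0L]
      if (length(full) < 2L) next
      s <- sample(full, min(3L, length(full)))
      joint <- prod(conditional_prob(m, s, d)) *
        (m$disease_counts[[d]] / m$n_records) /
        prod(marginal_prob(m, s, "empirical"))
      ratio <- score_disease(m, s, d, cfg)
      expect_equal(ratio, joint, tolerance = 1e-12)
    }
  }
})

test_that("log-form ranking matches product-form ranking absent underflow", {
  set.seed(202)
  for (rep in 1:15) {
    recs <- random_corpus(sample(2:4, 1), sample(4:6, 1), 30L)
    m <- nb_fit(recs)
    input <- sample(m$symptoms, sample(2:4, 1))
    for (weighted in c(FALSE, TRUE)) {
      pp <- predict(m, input,
                    nb_variant("empirical", "product", weighted = weighted,
                               top_k = 10L))
      pl <- predict(m, input,
                    nb_variant("empirical", "log", weighted = weighted,
                               top_k = 10L))
      if (nrow(pp) > 0L && all(pp$score > 0)) {
        expect_equal(pl$disease, pp$disease)
        expect_equal(pl$score, log(pp$score), tolerance = 1e-9)
      }
    }
  }
})

test_that("w = 1 makes weighted scoring bitwise-equal to unweighted", {
  set.seed(303)
  for (rep in 1:10) {
    recs <- random_corpus(3L, 5L, 25L)
    m <- nb_fit(recs)
    input <- sample(m$symptoms, 3L)
    for (form in c("product", "log")) {
      w1 <- predict(m, input, nb_variant("empirical", form,
                                         weighted = TRUE, w = 1))
      un <- predict(m, input, nb_variant("empirical", form,
                                         weighted = FALSE))
      expect_identical(w1$score, un$score)
      expect_identical(w1$disease, un$disease)
    }
  }
})

test_that("weighting cannot reorder when all candidates cooccur with all mains", {
  # if every candidate cooccurs with each of the first n_main symptoms,
  # all scores scale by w^n_main and the ranking is unchanged
  set.seed(404)
  for (rep in 1:20) {
    recs <- random_corpus(3L, 4L, 40L)
    m <- nb_fit(recs)
    input <- sample(m$symptoms, 3L)
    cand <- candidate_diseases(m, input)
    all_cooc <- all(m$pair_counts[cand, input, drop = FALSE] > 0L)
    if (!all_cooc) next
    pw <- predict(m, input, nb_variant("none", "product", weighted = TRUE,
                                       w = 3, top_k = 10L))
    pu <- predict(m, input, nb_variant("none", "product", top_k = 10L))
    expect_equal(pw$disease, pu$disease)
    expect_equal(pw$score, pu$score * 3^3, tolerance = 1e-12)
  }
})

test_that("duplicating every record m times preserves fully-observed scores", {
  # all MLE ratios (conditional, marginal, prior) are count-scale
  # invariant, so any score built solely from cooccurring pairs is
  # unchanged; smoothed operators for never-seen pairs shrink as the
  # corpus grows (more data is stronger evidence against the pair)
  set.seed(505)
  recs <- random_corpus(3L, 5L, 20L)
  m1 <- nb_fit(recs)
  m3 <- nb_fit(dplyr::bind_rows(recs, recs, recs))
  input <- sample(m1$symptoms, 3L)
  cand <- candidate_diseases(m1, input)
  full <- cand[rowSums(m1$pair_counts[cand, input, drop = FALSE] == 0L) == 0L]
  expect_gt(length(full), 0L)
  for (method in c("prior", "noprior", "log", "uniform")) {
    for (weighted in c(FALSE, TRUE)) {
      cfg <- method_config(method, weighted)
      for (d in full) {
        expect_equal(score_disease(m3, input, d, cfg),
                     score_disease(m1, input, d, cfg), tolerance = 1e-12)
      }
    }
  }
  # smoothed operators move down, never up, under duplication
  cfg <- nb_variant("empirical", "product")
  for (d in setdiff(cand, full)) {
    s0 <- input[m1$pair_counts[d, input] == 0L]
    expect_true(all(feature_operator(m3, s0, d, cfg) <=
                      feature_operator(m1, s0, d, cfg)))
  }
})

test_that("on a balanced corpus the uniform marginal equals the empirical one", {
  set.seed(606)
  for (rep in 1:5) {
    recs <- random_corpus(3L, 5L, 30L, balanced = TRUE)
    m <- nb_fit(recs)
    emp <- marginal_prob(m, m$symptoms, "empirical")
    uni <- marginal_prob(m, m$symptoms, "uniform")
    expect_equal(uni, emp, tolerance = 1e-14)
    # hence equal-probability and empirical-prior variants differ only by
    # a constant prior factor: identical rankings
    input <- sample(m$symptoms, 3L)
    pe <- predict(m, input, nb_variant("empirical", "product", top_k = 10L))
    pu <- predict(m, input, nb_variant("uniform", "product", top_k = 10L))
    expect_equal(pe$disease, pu$disease)
  }
})

test_that("every candidate scores positive (finite in log form)", {
  set.seed(707)
  for (rep in 1:10) {
    recs <- random_corpus(4L, 6L, 30L)
    m <- nb_fit(recs)
    input <- sample(m$symptoms, 4L)
    for (method in c("prior", "noprior", "log", "uniform")) {
      p <- predict(m, input, method_config(method, weighted = TRUE, top_k = 10))
      if (method == "log") {
        expect_true(all(is.finite(p$score)))
      } else {
        expect_true(all(p$score > 0))
      }
      # candidate restriction: every ranked disease cooccurs with an input
      for (d in p$disease) {
        expect_true(any(m$pair_counts[d, input] > 0L))
      }
    }
  }
})

test_that("oversampling to balance reproduces the analytic uniform marginal", {
  set.seed(808)
  recs <- random_corpus(3L, 5L, 24L)
  over <- oversample_balanced(recs)
  expect_equal(length(unique(table(over$disease))), 1L)
  m <- nb_fit(recs)
  mo <- nb_fit(over)
  expect_equal(marginal_prob(mo, m$symptoms, "empirical"),
               marginal_prob(m, m$symptoms, "uniform"), tolerance = 1e-12)
})
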