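test_that("fit counts records, diseases, symptoms and cooccurring pairs", {
  m <- nb_fit(toy_corpus())
  expect_equal(m$n_records, 4L)
  expect_equal(unname(m$disease_counts[c("A", "B")]), c(2L, 2L))
  expect_equal(unname(m$symptom_counts[c("s1", "s2", "s3")]), c(2, 2, 3))
  expect_equal(m$pair_counts["A", "s1"], 2L)
  expect_equal(m$pair_counts["B", "s1"], 0L)

  single <- nb_fit(toy_corpus()[1, ])
  expect_equal(single$n_records, 1L)
  expect_equal(unname(single$pair_counts["A", c("s1", "s2")]), c(1L, 1L))

  doubled <- nb_fit(dplyr::bind_rows(toy_corpus(), toy_corpus()))
  expect_equal(doubled$pair_counts, m$pair_counts * 2L)
  expect_equal(doubled$n_records, 8L)

  expect_error(nb_fit(toy_corpus()[0, ]), "empty")
})

test_that("count invariants hold on random corpora", {
  set.seed(11)
  for (rep in 1:5) {
    recs <- random_corpus(n_diseases = 4L, n_symptoms = 6L, n_records = 40L)
    m <- nb_fit(recs)
    expect_equal(sum(m$disease_counts), m$n_records)
    # single-diagnosis corpus: N(s) = sum_d N(d,s)
    expect_equal(unname(colSums(m$pair_counts)), unname(m$symptom_counts))
    expect_true(all(m$pair_counts <=
                      outer(m$disease_counts, rep(1L, ncol(m$pair_counts)))))
    expect_true(all(sweep(m$pair_counts, 2, m$symptom_counts, "<=")))
  }
})

test_that("conditional and marginal probabilities match hand counts", {
  m <- nb_fit(toy_corpus())
  expect_equal(conditional_prob(m, "s1", "A"), 1.0)
  expect_equal(conditional_prob(m, "s1", "B"), 0.0)
  expect_equal(conditional_prob(m, "s3", "B"), 1.0)
  expect_error(conditional_prob(m, "s1", "Z"), "unknown disease")

  expect_equal(marginal_prob(m, "s3", "empirical"), 0.75)
  # balanced toy: uniform-mixture marginal coincides with empirical
  expect_equal(marginal_prob(m, "s3", "uniform"), 0.75)
  expect_error(marginal_prob(m, "zzz"), "unknown symptom")

  # imbalanced: N(A)=3, N(B)=1, s only in A at rate 1 -> 0.75 vs 0.5
  imb <- tibble::tibble(
    disease = c("A", "A", "A", "B"),
    symptoms = list("s", "s", "s", "t")
  )
  mi <- nb_fit(imb)
  expect_equal(marginal_prob(mi, "s", "empirical"), 0.75)
  expect_equal(marginal_prob(mi, "s", "uniform"), 0.5)
})

test_that("feature operator uses MLE when cooccurring, smoothing otherwise", {
  m <- nb_fit(toy_corpus())
  cfg <- nb_variant("empirical", "product")
  expect_equal(feature_operator(m, "s1", "A", cfg), 2.0)
  expect_equal(feature_operator(m, "s2", "A", cfg), 1.0)
  # no cooccurrence: (1/(2 + 1*3)) / 0.5 = 0.4
  expect_equal(feature_operator(m, "s1", "B", cfg), 0.4)
  # smoothed operator is positive and below every cooccurring operator
  # for the same symptom here
  expect_gt(feature_operator(m, "s1", "B", cfg), 0)
  expect_lt(feature_operator(m, "s1", "B", cfg),
            feature_operator(m, "s1", "A", cfg))
})

test_that("candidate set is exactly the cooccurring diseases", {
  m <- nb_fit(toy_corpus())
  expect_equal(candidate_diseases(m, "s1"), "A")
  expect_equal(candidate_diseases(m, "s2"), c("A", "B"))
  expect_equal(candidate_diseases(m, "unknown"), character())
})

test_that("scores match the hand-derived toy values", {
  m <- nb_fit(toy_corpus())
  unw <- nb_variant("none", "product")
  expect_identical(score_disease(m, c("s1", "s2"), "A", unw), 2.0)
  expect_identical(score_disease(m, c("s1", "s2"), "B", unw), 0.4)
  w2 <- nb_variant("none", "product", weighted = TRUE, w = 2)
  expect_identical(score_disease(m, c("s1", "s2"), "A", w2), 8.0)
  # (B,s1) has no cooccurrence so no weight; (B,s2) gets w=2
  expect_identical(score_disease(m, c("s1", "s2"), "B", w2), 0.8)
  expect_error(score_disease(m, "s1", "B", unw), "not a candidate")
})

test_that("predict ranks, truncates, breaks ties by label, reports unknowns", {
  m <- nb_fit(toy_corpus())
  cfg <- nb_variant("none", "product")
  p <- predict(m, c("s1", "s2"), cfg)
  expect_equal(p$disease, c("A", "B"))
  expect_equal(p$score, c(2.0, 0.4))
  expect_equal(attr(p, "status"), "ok")

  # s2 alone scores A and B both at 1.0 -> lexicographic tie-break
  tie <- predict(m, "s2", cfg)
  expect_equal(tie$disease, c("A", "B"))
  expect_equal(tie$score, c(1.0, 1.0))

  none <- predict(m, "unknown-only", cfg)
  expect_equal(attr(none, "status"), "no_candidates")
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "unknown_symptoms"), "unknown-only")

  # comma string input segments like a vector (fullwidth too)
  expect_equal(predict(m, "s1，s2", cfg)$score, p$score)

  # truncation to top_k
  p1 <- predict(m, c("s1", "s2"), nb_variant("none", top_k = 1L))
  expect_equal(p1$disease, "A")
})

test_that("model JSON serialisation round-trips all counts exactly", {
  m <- nb_fit(toy_corpus())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$pair_counts, m$pair_counts)
  expect_identical(back$disease_counts, m$disease_counts)
  expect_equal(back$symptom_counts, m$symptom_counts)
  expect_identical(back$n_records, m$n_records)
  # scoring through the round-tripped model is unchanged
  cfg <- nb_variant("empirical", "product", weighted = TRUE)
  expect_identical(
    predict(back, c("s1", "s2"), cfg)$score,
    predict(m, c("s1", "s2"), cfg)$score
  )
})

test_that("tidy and glance summarise the fitted model", {
  m <- nb_fit(toy_corpus())
  td <- tidy(m)
  expect_equal(nrow(td), 5L)  # 5 cooccurring pairs
  expect_equal(td$p_conditional[td$disease == "A" & td$symptom == "s1"], 1.0)
  gl <- glance(m)
  expect_equal(gl$n_records, 4L)
  expect_equal(gl$n_pairs, 5L)
})
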