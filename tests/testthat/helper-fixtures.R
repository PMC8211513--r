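# Shared fixtures: the 4-record toy corpus, a random small-corpus
# generator, and a brute-force reference scorer that evaluates the printed
# formulas literally (plain loops, no shared code with the package's
# matrix kernel).

toy_corpus <- function() {
  tibble::tibble(
    disease = c("A", "A", "B", "B"),
    symptoms = list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3"), "s3"),
    source_id = c("r1", "r2", "r3", "r4")
  )
}

random_corpus <- function(n_diseases = 3L, n_symptoms = 5L, n_records = 30L,
                          balanced = FALSE) {
  diseases <- LETTERS[seq_len(n_diseases)]
  vocab <- paste0("s", seq_len(n_symptoms))
  d <- if (balanced) {
    rep(diseases, length.out = n_records)
  } else {
    sample(diseases, n_records, replace = TRUE)
  }
  symptoms <- lapply(seq_len(n_records), function(i) {
    k <- sample.int(min(4L, n_symptoms), 1L)
    sample(vocab, k)
  })
  tibble::tibble(disease = d, symptoms = symptoms,
                 source_id = sprintf("r%d", seq_len(n_records)))
}

# ---- brute-force reference ------------------------------------------------

bf_counts <- function(records) {
  n <- nrow(records)
  nd <- table(records$disease)
  vocab <- sort(unique(unlist(records$symptoms)))
  ns <- sapply(vocab, function(s) {
    sum(vapply(records$symptoms, function(x) s %in% unique(x), logical(1)))
  })
  nds <- list()
  for (d in names(nd)) {
    rows <- records$symptoms[records$disease == d]
    nds[[d]] <- sapply(vocab, function(s) {
      sum(vapply(rows, function(x) s %in% unique(x), logical(1)))
    })
  }
  list(n = n, nd = nd, ns = ns, nds = nds, vocab = vocab,
       diseases = sort(names(nd)))
}

bf_operator <- function(cts, s, d, prior = "empirical", alpha = 1) {
  pair <- cts$nds[[d]][[s]]
  cond <- if (pair > 0) {
    pair / as.numeric(cts$nd[[d]])
  } else {
    alpha / (as.numeric(cts$nd[[d]]) + alpha * length(cts$vocab))
  }
  marg <- if (prior == "uniform") {
    mean(sapply(cts$diseases,
                function(dd) cts$nds[[dd]][[s]] / as.numeric(cts$nd[[dd]])))
  } else {
    cts$ns[[s]] / cts$n
  }
  cond / marg
}

bf_score <- function(cts, symptoms, d, method, weighted = FALSE, w = 2,
                     n_main = 3, alpha = 1) {
  prior_mode <- switch(method, prior = "empirical", noprior = "none",
                       log = "empirical", uniform = "uniform")
  total <- if (method == "log") 0 else 1
  for (i in seq_along(symptoms)) {
    s <- symptoms[i]
    op <- bf_operator(cts, s, d, prior_mode, alpha)
    g <- 1
    if (weighted && i <= n_main && cts$nds[[d]][[s]] > 0) g <- w
    total <- if (method == "log") total + log(g * op) else total * g * op
  }
  pterm <- switch(prior_mode,
    empirical = as.numeric(cts$nd[[d]]) / cts$n,
    none = 1,
    uniform = 1 / length(cts$diseases)
  )
  if (method == "log") total + log(pterm) else total * pterm
}

bf_predict <- function(cts, symptoms, method, weighted = FALSE, w = 2,
                       n_main = 3, alpha = 1, top_k = 3) {
  symptoms <- unique(symptoms)
  symptoms <- symptoms[symptoms %in% cts$vocab]
  cand <- Filter(function(d) any(sapply(symptoms,
                                        function(s) cts$nds[[d]][[s]] > 0)),
                 cts$diseases)
  if (length(cand) == 0) {
    return(tibble::tibble(disease = character(), score = double()))
  }
  sc <- sapply(cand, function(d) {
    bf_score(cts, symptoms, d, method, weighted, w, n_main, alpha)
  })
  ord <- order(-sc, cand)
  tibble::tibble(disease = cand[ord], score = unname(sc[ord]))[
    seq_len(min(top_k, length(cand))), ]
}

# Tie-aware ranking comparison: the two score routes may differ by a few
# ulps, so diseases whose scores are equal within tolerance form one tie
# group and may appear in any order within it.
expect_rank_equiv <- function(got, want, tol = 1e-9) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got) == 0L) return(invisible())
  expect_equal(got$score, want$score, tolerance = tol)
  scale <- pmax(abs(want$score), 1e-300)
  brk <- c(TRUE, abs(diff(want$score)) > tol * scale[-1])
  grp <- cumsum(brk)
  for (g in unique(grp)) {
    expect_setequal(got$disease[grp == g], want$disease[grp == g])
  }
}

# map a variant-grid method label to an nb_variant
method_config <- function(method, weighted, w = 2, alpha = 1, top_k = 3) {
  switch(method,
    prior = nb_variant("empirical", "product", weighted = weighted, w = w,
                       alpha = alpha, top_k = top_k),
    noprior = nb_variant("none", "product", weighted = weighted, w = w,
                         alpha = alpha, top_k = top_k),
    log = nb_variant("empirical", "log", weighted = weighted, w = w,
                     alpha = alpha, top_k = top_k),
    uniform = nb_variant("uniform", "product", weighted = weighted, w = w,
                         alpha = alpha, top_k = top_k)
  )
}
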