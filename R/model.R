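#' Fit the cooccurrence model from a diagnosis corpus
#'
#' Counts everything the scoring formulas need, under a record-level
#' presence/absence (Bernoulli) event model: a symptom contributes once per
#' record no matter how it was entered. The fitted object holds the total
#' record count \eqn{N}, per-disease counts \eqn{N(d)}, per-symptom record
#' counts \eqn{N(s)}, and the disease-symptom cooccurrence counts
#' \eqn{N(d,s)} as a dense integer matrix.
#'
#' @param records A record tibble ([as_records()] is applied), one single
#'   disease per record.
#' @return An object of class `nb_model`.
#' @examples
#' toy <- tibble::tibble(
#'   disease = c("A", "A", "B", "B"),
#'   symptoms = list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3"), "s3")
#' )
#' m <- nb_fit(toy)
#' glance(m)
#' @export
nb_fit <- function(records) {
  records <- as_records(records)
  if (nrow(records) == 0L) abort("cannot fit on an empty corpus")
  if (any(lengths(records$symptoms) == 0L)) {
    abort("every record must have at least one symptom")
  }
  diseases <- sort(unique(records$disease))
  symptoms <- sort(unique(unlist(records$symptoms)))
  pair <- matrix(0L, nrow = length(diseases), ncol = length(symptoms),
                 dimnames = list(diseases, symptoms))
  di <- match(records$disease, diseases)
  for (i in seq_len(nrow(records))) {
    si <- match(records$symptoms[[i]], symptoms)
    pair[di[i], si] <- pair[di[i], si] + 1L
  }
  structure(
    list(
      n_records = nrow(records),
      diseases = diseases,
      symptoms = symptoms,
      disease_counts = setNames(tabulate(di, length(diseases)), diseases),
      symptom_counts = setNames(colSums(pair), symptoms),
      pair_counts = pair
    ),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf(
    "<nb_model> %d records, %d diseases, %d symptoms, %d cooccurring pairs\n",
    x$n_records, length(x$diseases), length(x$symptoms),
    sum(x$pair_counts > 0L)
  ))
  invisible(x)
}

#' @describeIn nb_fit One row per cooccurring (disease, symptom) pair with
#'   counts, the conditional probability and the empirical marginal.
#' @param x An `nb_model`.
#' @param ... Unused.
#' @export
tidy.nb_model <- function(x, ...) {
  idx <- which(x$pair_counts > 0L, arr.ind = TRUE)
  tibble(
    disease = x$diseases[idx[, 1L]],
    symptom = x$symptoms[idx[, 2L]],
    n_pair = x$pair_counts[idx],
    p_conditional = unname(x$pair_counts[idx] / x$disease_counts[idx[, 1L]]),
    p_marginal = unname(x$symptom_counts[idx[, 2L]] / x$n_records)
  ) %>% arrange(.data$disease, .data$symptom)
}

#' @describeIn nb_fit One-row model summary.
#' @export
glance.nb_model <- function(x, ...) {
  tibble(
    n_records = x$n_records,
    n_diseases = length(x$diseases),
    n_symptoms = length(x$symptoms),
    n_pairs = sum(x$pair_counts > 0L)
  )
}

#' Conditional probability of a symptom given a disease
#'
#' Maximum-likelihood estimate \eqn{\hat P(s|d) = N(d,s)/N(d)}, unsmoothed:
#' smoothing applies only inside [feature_operator()] for pairs never seen
#' together.
#'
#' @param model An [nb_fit()] model.
#' @param symptom,disease Term labels (vectorised, recycled).
#' @return Numeric vector of probabilities (0 for a symptom absent from the
#'   model's vocabulary).
#' @export
conditional_prob <- function(model, symptom, disease) {
  stopifnot(inherits(model, "nb_model"))
  di <- match(disease, model$diseases)
  if (anyNA(di)) abort("unknown disease")
  si <- match(symptom, model$symptoms)
  n_pair <- ifelse(is.na(si), 0L, model$pair_counts[cbind(di, si)])
  unname(n_pair / model$disease_counts[di])
}

#' Marginal probability of a symptom
#'
#' Empirical (and no-prior) variants use the corpus frequency
#' \eqn{\hat P(s) = N(s)/N}. The uniform (equal-probability) variant uses
#' the marginal a class-balanced corpus would induce,
#' \eqn{\hat P(s) = (1/|D|) \sum_d \hat P(s|d)} — the exact limit of
#' oversampling every disease to the same record count.
#'
#' @param model An [nb_fit()] model.
#' @param symptom Symptom label(s), must be in the vocabulary.
#' @param prior `"empirical"`, `"none"` or `"uniform"`.
#' @return Numeric vector of probabilities.
#' @export
marginal_prob <- function(model, symptom,
                          prior = c("empirical", "none", "uniform")) {
  stopifnot(inherits(model, "nb_model"))
  prior <- arg_match(prior)
  si <- match(symptom, model$symptoms)
  if (anyNA(si)) abort("unknown symptom")
  if (prior == "uniform") {
    cond <- model$pair_counts[, si, drop = FALSE] / model$disease_counts
    unname(colMeans(cond))
  } else {
    unname(model$symptom_counts[si] / model$n_records)
  }
}

#' Per-symptom likelihood-ratio feature operator
#'
#' The multiplicative unit of the scoring: \eqn{\hat P(s|d)/\hat P(s)} when
#' the pair cooccurs in the training corpus, and a Laplace-smoothed stand-in
#' \eqn{[\alpha/(N(d) + \alpha |V|)]/\hat P(s)} otherwise — strictly
#' positive, and very small relative to any cooccurring operator for the
#' same symptom, so no candidate's score collapses to zero. The marginal in
#' the denominator follows the variant's prior mode. No main-symptom
#' weighting is applied here.
#'
#' @param model An [nb_fit()] model.
#' @param symptom,disease Term labels (vectorised, recycled).
#' @param config An [nb_variant()].
#' @return Positive numeric vector.
#' @export
feature_operator <- function(model, symptom, disease, config = nb_variant()) {
  stopifnot(inherits(model, "nb_model"), inherits(config, "nb_variant"))
  di <- match(disease, model$diseases)
  si <- match(symptom, model$symptoms)
  if (anyNA(di)) abort("unknown disease")
  if (anyNA(si)) abort("unknown symptom")
  n_pair <- model$pair_counts[cbind(di, si)]
  n_d <- model$disease_counts[di]
  marg <- marginal_prob(model, symptom, config$prior)
  v <- length(model$symptoms)
  cond <- ifelse(n_pair > 0L, n_pair / n_d,
                 config$alpha / (n_d + config$alpha * v))
  unname(cond / marg)
}

#' Diseases involved in a symptom list
#'
#' A disease is a candidate iff it cooccurs with at least one of the input
#' symptoms in the training corpus; symptoms outside the vocabulary are
#' ignored here (callers report them).
#'
#' @param model An [nb_fit()] model.
#' @param symptoms Character vector of symptom terms.
#' @return Character vector of candidate diseases (possibly empty), in model
#'   order.
#' @export
candidate_diseases <- function(model, symptoms) {
  stopifnot(inherits(model, "nb_model"))
  si <- match(unique(symptoms), model$symptoms)
  si <- si[!is.na(si)]
  if (length(si) == 0L) return(character())
  model$diseases[rowSums(model$pair_counts[, si, drop = FALSE] > 0L) > 0L]
}

# prior term of a variant: P(d), 1, or 1/|D|
prior_term <- function(model, disease, config) {
  switch(config$prior,
    empirical = model$disease_counts[match(disease, model$diseases)] /
      model$n_records,
    none = rep(1, length(disease)),
    uniform = rep(1 / length(model$diseases), length(disease))
  )
}

#' Score one candidate disease for an ordered symptom list
#'
#' Product form: \eqn{\prod_i g_i\,op_i \times \mathrm{prior}}, where
#' \eqn{op_i} is the [feature_operator()] of the i-th symptom and
#' \eqn{g_i = w} when main-symptom weighting is on, the symptom sits in the
#' first `n_main` positions, and it cooccurs with the disease (else
#' \eqn{g_i = 1}). Log form: \eqn{\sum_i \log(g_i\,op_i) + \log \mathrm{prior}}.
#' The product form is computed literally — it can underflow on very long
#' symptom lists; the log form is the safe branch.
#'
#' @param model An [nb_fit()] model.
#' @param symptoms Ordered character vector; terms outside the vocabulary
#'   are dropped (order otherwise preserved), duplicates removed.
#' @param disease A candidate disease (error if it has no cooccurring input
#'   symptom).
#' @param config An [nb_variant()].
#' @return A single numeric score.
#' @export
score_disease <- function(model, symptoms, disease, config = nb_variant()) {
  stopifnot(inherits(model, "nb_model"), length(disease) == 1L)
  symptoms <- unique(symptoms)
  symptoms <- symptoms[symptoms %in% model$symptoms]
  if (!disease %in% candidate_diseases(model, symptoms)) {
    abort(sprintf("'%s' is not a candidate for these symptoms", disease))
  }
  op <- feature_operator(model, symptoms, disease, config)
  di <- match(disease, model$diseases)
  si <- match(symptoms, model$symptoms)
  cooc <- model$pair_counts[di, si] > 0L
  g <- rep(1, length(symptoms))
  if (config$weighted) {
    main <- seq_along(symptoms) <= config$n_main
    g[main & cooc] <- config$w
  }
  pt <- unname(prior_term(model, disease, config))
  if (config$form == "log") sum(log(g * op)) + log(pt) else prod(g * op) * pt
}

#' Rank candidate diseases for a symptom list
#'
#' Normalises the input (dedup, drop terms unseen in training), scores every
#' candidate disease under the variant, sorts by descending score with ties
#' broken by disease label, and truncates to `top_k`.
#'
#' @param object An [nb_fit()] model.
#' @param symptoms Ordered character vector of symptom terms (or a single
#'   comma-separated string, which is segmented first).
#' @param config An [nb_variant()].
#' @param ... Unused.
#' @return A tibble of class `nb_prediction` with columns `rank`, `disease`,
#'   `score`; attributes `status` (`"ok"` or `"no_candidates"`),
#'   `unknown_symptoms` (input terms not in the vocabulary) and
#'   `candidates_considered`.
#' @examples
#' toy <- tibble::tibble(
#'   disease = c("A", "A", "B", "B"),
#'   symptoms = list(c("s1", "s2"), c("s1", "s3"), c("s2", "s3"), "s3")
#' )
#' predict(nb_fit(toy), c("s1", "s2"), nb_variant("none"))
#' @export
predict.nb_model <- function(object, symptoms, config = nb_variant(), ...) {
  if (length(symptoms) == 1L && grepl("[,，]", symptoms)) {
    symptoms <- segment_symptoms(symptoms)[[1L]]
  }
  symptoms <- unique(as.character(symptoms))
  known <- symptoms %in% object$symptoms
  unknown <- symptoms[!known]
  symptoms <- symptoms[known]

  cand <- candidate_diseases(object, symptoms)
  if (length(cand) == 0L) {
    out <- tibble(rank = integer(), disease = character(), score = double())
    return(new_prediction(out, "no_candidates", unknown, 0L))
  }
  scores <- score_matrix(object, list(symptoms), config, cand)[1L, ]
  ord <- order(-scores, cand)
  keep <- head(ord, config$top_k)
  out <- tibble(
    rank = seq_along(keep),
    disease = cand[keep],
    score = unname(scores[keep])
  )
  new_prediction(out, "ok", unknown, length(cand))
}

new_prediction <- function(tbl, status, unknown, n_cand) {
  attr(tbl, "status") <- status
  attr(tbl, "unknown_symptoms") <- unknown
  attr(tbl, "candidates_considered") <- n_cand
  class(tbl) <- c("nb_prediction", class(tbl))
  tbl
}

# Dense scoring kernel shared by predict() and the evaluation loop.
# symptom_lists: list of character vectors already restricted to the
# vocabulary, order preserved. Returns a length(symptom_lists) x
# length(cand) matrix of scores (NA where the disease is not a candidate
# for that record).
score_matrix <- function(model, symptom_lists, config,
                         cand = model$diseases) {
  v <- length(model$symptoms)
  ci <- match(cand, model$diseases)
  n_d <- model$disease_counts[ci]
  pairs <- model$pair_counts[ci, , drop = FALSE]
  cond <- pairs / n_d
  marg <- if (config$prior == "uniform") {
    colMeans(model$pair_counts / model$disease_counts)
  } else {
    model$symptom_counts / model$n_records
  }
  smooth <- config$alpha / (n_d + config$alpha * v)
  op <- sweep(ifelse(pairs > 0L, cond, smooth), 2L, marg, "/")
  cooc <- pairs > 0L
  prior <- switch(config$prior,
    empirical = unname(n_d / model$n_records),
    none = rep(1, length(ci)),
    uniform = rep(1 / length(model$diseases), length(ci))
  )

  out <- matrix(NA_real_, nrow = length(symptom_lists), ncol = length(cand),
                dimnames = list(NULL, cand))
  lw <- log(config$w)
  for (r in seq_along(symptom_lists)) {
    si <- match(symptom_lists[[r]], model$symptoms)
    if (length(si) == 0L) next
    ops <- op[, si, drop = FALSE]
    is_cand <- rowSums(cooc[, si, drop = FALSE]) > 0L
    g <- matrix(1, nrow = length(ci), ncol = length(si))
    if (config$weighted && config$n_main > 0L) {
      main <- seq_along(si) <= config$n_main
      g[, main] <- ifelse(cooc[, si[main], drop = FALSE], config$w, 1)
    }
    sc <- if (config$form == "log") {
      rowSums(log(ops)) +
        (if (config$weighted) rowSums((g > 1) * lw) else 0) +
        log(prior)
    } else {
      apply(g * ops, 1L, prod) * prior
    }
    sc[!is_cand] <- NA_real_
    out[r, ] <- sc
  }
  out
}
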