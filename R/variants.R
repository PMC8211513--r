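#' Configure a Naive Bayes scoring variant
#'
#' Each variant scores a candidate disease \eqn{d} for an ordered symptom
#' list by combining per-symptom likelihood-ratio operators
#' \eqn{P(s|d)/P(s)} with a prior term, optionally up-weighting the first
#' `n_main` ("main") symptoms. The eight variants compared in practice are
#' the grid [nb_variants()]: \{empirical prior, no prior, log form,
#' equal probability\} x \{weighted, unweighted\}.
#'
#' @param prior How the class prior enters: `"empirical"` multiplies by
#'   \eqn{P(d) = N(d)/N}; `"none"` omits it (the score is then the
#'   rate of change of the posterior over the prior); `"uniform"` is the
#'   equal-probability treatment — prior \eqn{1/|D|} and, crucially, the
#'   symptom marginal recomputed as the uniform mixture
#'   \eqn{P(s) = (1/|D|)\sum_d P(s|d)}, the analytic limit of oversampling
#'   every class to the same size.
#' @param form `"product"` computes the score as the literal product (and may
#'   underflow on long symptom lists); `"log"` sums logs and is the
#'   numerically safe branch.
#' @param weighted Apply the main-symptom weight coefficient?
#' @param w Weight coefficient, `> 1` to have an effect (default 2); `w = 1`
#'   is allowed and makes the weighted variant coincide with the unweighted
#'   one. Applied only when the symptom actually cooccurs with the candidate
#'   disease in the training corpus.
#' @param n_main How many leading symptoms count as main symptoms (default 3).
#' @param alpha Laplace smoothing constant for disease-symptom pairs never
#'   seen together (default 1).
#' @param top_k Length of the recommendation list (default 3).
#' @return A list of class `nb_variant`.
#' @export
nb_variant <- function(prior = c("empirical", "none", "uniform"),
                       form = c("product", "log"),
                       weighted = FALSE, w = 2, n_main = 3L,
                       alpha = 1, top_k = 3L) {
  prior <- arg_match(prior)
  form <- arg_match(form)
  stopifnot(is.numeric(w), length(w) == 1L, w > 0,
            n_main >= 0L, alpha > 0, top_k >= 1L)
  structure(
    list(prior = prior, form = form, weighted = isTRUE(weighted),
         w = as.numeric(w), n_main = as.integer(n_main),
         alpha = as.numeric(alpha), top_k = as.integer(top_k)),
    class = "nb_variant"
  )
}

#' The eight-variant comparison grid
#'
#' Four scoring methods (empirical prior in product form, no prior, log
#' form with empirical prior, equal probability) crossed with main-symptom
#' weighting on/off.
#'
#' @inheritParams nb_variant
#' @return A tibble with columns `variant` (label), `method`, `weighted`,
#'   and a list-column `config` of [nb_variant()] objects.
#' @export
nb_variants <- function(w = 2, n_main = 3L, alpha = 1, top_k = 3L) {
  cells <- tibble(
    method = rep(c("prior", "noprior", "log", "uniform"), each = 2L),
    weighted = rep(c(TRUE, FALSE), times = 4L)
  )
  cells %>%
    mutate(
      variant = paste0(.data$method,
                       ifelse(.data$weighted, "+weighted", "+unweighted")),
      config = map2(.data$method, .data$weighted, function(m, wt) {
        switch(m,
          prior = nb_variant("empirical", "product", weighted = wt, w = w,
                             n_main = n_main, alpha = alpha, top_k = top_k),
          noprior = nb_variant("none", "product", weighted = wt, w = w,
                               n_main = n_main, alpha = alpha, top_k = top_k),
          log = nb_variant("empirical", "log", weighted = wt, w = w,
                           n_main = n_main, alpha = alpha, top_k = top_k),
          uniform = nb_variant("uniform", "product", weighted = wt, w = w,
                               n_main = n_main, alpha = alpha, top_k = top_k)
        )
      })
    ) %>%
    select("variant", "method", "weighted", "config")
}

#' @export
print.nb_variant <- function(x, ...) {
  cat(sprintf(
    "<nb_variant> prior=%s form=%s weighted=%s (w=%g, n_main=%d) alpha=%g top_k=%d\n",
    x$prior, x$form, x$weighted, x$w, x$n_main, x$alpha, x$top_k
  ))
  invisible(x)
}
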