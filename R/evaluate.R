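#' Assign records to cross-validation folds
#'
#' Stratified by disease where the class has at least `k` records, so no
#' disease is entirely absent from a training split; classes with fewer
#' records than folds fall back to plain random assignment. Deterministic
#' under a fixed seed.
#'
#' @param records A record tibble.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @param stratify Stratify by disease? Default `TRUE`.
#' @return An integer vector of fold ids in `1:k`, one per record; folds
#'   partition the corpus.
#' @export
kfold_assign <- function(records, k = 3L, seed = 1L, stratify = TRUE) {
  records <- as_records(records)
  n <- nrow(records)
  if (k < 2L) abort("k must be at least 2")
  if (k > n) abort("k exceeds the number of records")
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratify) {
      for (d in unique(records$disease)) {
        idx <- which(records$disease == d)
        if (length(idx) >= k) {
          fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
        } else {
          fold[idx] <- sample(seq_len(k), length(idx), replace = TRUE)
        }
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
  })
  fold
}

#' Top-k hit accuracy of a fitted model on held-out records
#'
#' A test record is a hit iff its true disease appears anywhere in the
#' top-`k` ranked recommendation; records for which no candidate disease
#' exists (none of their symptoms cooccur with any disease in training)
#' count as misses and are tallied separately.
#'
#' @param model An [nb_fit()] model fitted on data disjoint from
#'   `test_records`.
#' @param test_records A record tibble.
#' @param config An [nb_variant()]; its `top_k` sets the recommendation
#'   length (default 3).
#' @return A one-row tibble: `accuracy`, `n_test`, `n_hits`,
#'   `n_no_candidate`.
#' @export
hit_accuracy <- function(model, test_records, config = nb_variant()) {
  test_records <- as_records(test_records)
  if (nrow(test_records) == 0L) abort("empty test set")
  hits <- predict_hits(model, test_records, config)
  tibble(
    accuracy = mean(hits$hit),
    n_test = nrow(test_records),
    n_hits = sum(hits$hit),
    n_no_candidate = sum(hits$no_candidate)
  )
}

# Batch hit computation: one score_matrix pass per corpus, shared by
# hit_accuracy and the variant grid.
predict_hits <- function(model, test_records, config) {
  symptom_lists <- lapply(test_records$symptoms, function(s) {
    s <- unique(s)
    s[s %in% model$symptoms]
  })
  scores <- score_matrix(model, symptom_lists, config)
  labels <- colnames(scores)
  k <- config$top_k
  hit <- logical(nrow(test_records))
  no_cand <- logical(nrow(test_records))
  for (r in seq_len(nrow(test_records))) {
    sc <- scores[r, ]
    cand <- which(!is.na(sc))
    if (length(cand) == 0L) {
      no_cand[r] <- TRUE
      next
    }
    ord <- cand[order(-sc[cand], labels[cand])]
    hit[r] <- test_records$disease[r] %in% labels[head(ord, k)]
  }
  tibble(hit = hit, no_candidate = no_cand)
}

#' Cross-validated accuracy of all scoring variants on shared folds
#'
#' Runs k-fold cross-validation once and evaluates every variant on the
#' same train/test splits (a paired comparison), pooling hits over folds
#' (record-weighted) and also reporting per-fold accuracies.
#'
#' @param records A record tibble.
#' @param configs A variant grid as returned by [nb_variants()] (columns
#'   `variant` and `config`).
#' @param k Number of folds (default 3).
#' @param seed Integer seed controlling the fold assignment.
#' @param stratify Stratify folds by disease? Default `TRUE`.
#' @return A tibble of class `nb_grid`: one row per variant with `variant`,
#'   `method`, `weighted`, `accuracy` (pooled), `n_test`, `n_no_candidate`,
#'   and `per_fold` (list-column of per-fold accuracies). Attributes `seed`
#'   and `k` record the protocol.
#' @export
run_variant_grid <- function(records, configs = nb_variants(), k = 3L,
                             seed = 1L, stratify = TRUE) {
  records <- as_records(records)
  stopifnot(all(c("variant", "config") %in% names(configs)))
  fold <- kfold_assign(records, k = k, seed = seed, stratify = stratify)

  per_variant <- lapply(seq_len(nrow(configs)), function(i) {
    list(hits = 0L, n = 0L, no_cand = 0L, fold_acc = numeric(k))
  })
  for (f in seq_len(k)) {
    train <- records[fold != f, , drop = FALSE]
    test <- records[fold == f, , drop = FALSE]
    model <- nb_fit(train)
    for (i in seq_len(nrow(configs))) {
      h <- predict_hits(model, test, configs$config[[i]])
      pv <- per_variant[[i]]
      pv$hits <- pv$hits + sum(h$hit)
      pv$n <- pv$n + nrow(test)
      pv$no_cand <- pv$no_cand + sum(h$no_candidate)
      pv$fold_acc[f] <- mean(h$hit)
      per_variant[[i]] <- pv
    }
  }

  out <- tibble(
    variant = configs$variant,
    method = if ("method" %in% names(configs)) configs$method else NA_character_,
    weighted = if ("weighted" %in% names(configs)) configs$weighted else NA,
    accuracy = map_dbl(per_variant, ~ .x$hits / .x$n),
    n_test = map_int(per_variant, ~ as.integer(.x$n)),
    n_no_candidate = map_int(per_variant, ~ as.integer(.x$no_cand)),
    per_fold = map(per_variant, ~ .x$fold_acc)
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("nb_grid", class(out))
  out
}

#' @export
tidy.nb_grid <- function(x, ...) {
  as_tibble(unclass(x)[setdiff(names(x), "per_fold")]) %>%
    mutate(fold = map(x$per_fold, ~ tibble(fold = seq_along(.x),
                                           fold_accuracy = .x))) %>%
    tidyr::unnest("fold")
}

#' @export
glance.nb_grid <- function(x, ...) {
  best <- which.max(x$accuracy)
  tibble(
    k = attr(x, "k"),
    seed = attr(x, "seed"),
    n_variants = nrow(x),
    best_variant = x$variant[best],
    best_accuracy = x$accuracy[best]
  )
}

#' Plot a variant-grid comparison
#'
#' Bar chart of pooled top-k accuracy per scoring method, weighted vs
#' unweighted side by side.
#'
#' @param object An `nb_grid` from [run_variant_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_grid <- function(object, ...) {
  df <- as_tibble(unclass(object)[c("method", "weighted", "accuracy")]) %>%
    mutate(weighting = ifelse(.data$weighted, "weighted", "unweighted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$accuracy,
                                   fill = .data$weighting)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "prior / form", y = "top-k hit accuracy",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write a variant grid as TSV plus a JSON run manifest
#'
#' @param grid An `nb_grid`.
#' @param dir Output directory (created if needed).
#' @return Paths of the two files written, invisibly.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- attr(grid, "k")
  flat <- as_tibble(unclass(grid)[setdiff(names(grid), "per_fold")])
  pf <- do.call(rbind, grid$per_fold)
  colnames(pf) <- sprintf("fold%d", seq_len(k))
  flat <- bind_cols(flat, as_tibble(pf))
  tsv <- file.path(dir, "variant_grid.tsv")
  readr::write_tsv(flat, tsv, progress = FALSE)
  manifest <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(
    list(seed = attr(grid, "seed"), k = k, variants = grid$variant),
    manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, manifest))
}
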