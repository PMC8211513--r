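#' Serialise a fitted model to JSON
#'
#' Writes every count and the vocabulary as integers; [read_model()] is an
#' exact inverse (round-trip equality of all counts).
#'
#' @param model An [nb_fit()] model.
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  nz <- which(model$pair_counts > 0L, arr.ind = TRUE)
  doc <- list(
    format = "dxbayes-model",
    version = 1L,
    n_records = model$n_records,
    diseases = model$diseases,
    symptoms = model$symptoms,
    disease_counts = unname(model$disease_counts),
    symptom_counts = unname(model$symptom_counts),
    pairs = list(
      disease = unname(nz[, 1L]),
      symptom = unname(nz[, 2L]),
      n = unname(model$pair_counts[nz])
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialised by [write_model()]
#'
#' @param path Path to the JSON document.
#' @return An `nb_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "dxbayes-model")) {
    abort("not a dxbayes model file")
  }
  diseases <- as.character(doc$diseases)
  symptoms <- as.character(doc$symptoms)
  pair <- matrix(0L, length(diseases), length(symptoms),
                 dimnames = list(diseases, symptoms))
  pair[cbind(doc$pairs$disease, doc$pairs$symptom)] <- as.integer(doc$pairs$n)
  structure(
    list(
      n_records = as.integer(doc$n_records),
      diseases = diseases,
      symptoms = symptoms,
      disease_counts = setNames(as.integer(doc$disease_counts), diseases),
      symptom_counts = setNames(as.numeric(doc$symptom_counts), symptoms),
      pair_counts = pair
    ),
    class = "nb_model"
  )
}

#' Replicate records until all disease classes are equally frequent
#'
#' The explicit oversampling realisation of the equal-probability variant:
#' each class is replicated to the least common multiple of the class
#' counts, so every disease ends with the same number of records. On the
#' balanced result, the empirical symptom marginal equals the uniform-
#' mixture marginal that `prior = "uniform"` computes analytically — this
#' function exists to verify that identity and should only be used on small
#' corpora (the LCM grows quickly).
#'
#' @param records A record tibble.
#' @return A record tibble with equal per-disease counts.
#' @export
oversample_balanced <- function(records) {
  records <- as_records(records)
  counts <- table(records$disease)
  lcm2 <- function(a, b) a / gcd2(a, b) * b
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  target <- Reduce(lcm2, as.numeric(counts))
  if (target > 1e6) abort("class-count LCM too large to oversample")
  reps <- target / as.numeric(counts[records$disease])
  out <- records[rep(seq_len(nrow(records)), times = reps), , drop = FALSE]
  out$source_id <- sprintf("%s#%d", out$source_id,
                           unlist(lapply(reps, seq_len)))
  out
}

#' @export
print.nb_prediction <- function(x, ...) {
  st <- attr(x, "status")
  if (identical(st, "no_candidates")) {
    cat("<nb_prediction> no candidate diseases for this input\n")
  } else {
    cat(sprintf("<nb_prediction> top %d of %d candidates\n",
                nrow(x), attr(x, "candidates_considered")))
    print(as_tibble(x))
  }
  un <- attr(x, "unknown_symptoms")
  if (length(un) > 0L) {
    cat("unknown symptoms (ignored):", paste(un, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.nb_prediction <- function(x, ...) {
  as_tibble(unclass(x)[c("rank", "disease", "score")])
}

#' @export
glance.nb_prediction <- function(x, ...) {
  tibble(
    status = attr(x, "status"),
    candidates_considered = attr(x, "candidates_considered"),
    n_ranked = nrow(x),
    n_unknown_symptoms = length(attr(x, "unknown_symptoms"))
  )
}
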