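#' Build a term lexicon from surface/canonical pairs
#'
#' A term lexicon maps surface forms of symptom and disease names (synonyms,
#' spelling variants) to a single canonical term, the way a clinical ontology
#' standardises free-text entries such as "Difficulty falling asleep" or
#' "Wake up midnight" to "Insomnia". Lookup keys are case-folded and
#' whitespace-trimmed; every canonical term is closed into the lexicon as a
#' fixed point, so normalisation is idempotent.
#'
#' @param entries A data frame with columns `surface` and `canonical`, and
#'   optionally `category` (`"disease"` or `"symptom"`). May have zero rows.
#' @return A tibble of class `dx_lexicon` with columns `key` (folded surface
#'   form), `surface`, `canonical`, `category`.
#' @details Two different surface forms may map to the same canonical term,
#'   but one surface form mapping to two different canonical terms is a
#'   contradiction and raises an error naming the offending term.
#' @examples
#' lex <- dx_lexicon(data.frame(
#'   surface = c("Wake up midnight", "Difficulty falling asleep"),
#'   canonical = "Insomnia"
#' ))
#' normalize_terms(c("wake up midnight", "Insomnia", "zzz"), lex)
#' @export
dx_lexicon <- function(entries = data.frame(surface = character(),
                                            canonical = character())) {
  entries <- as_tibble(entries)
  stopifnot(all(c("surface", "canonical") %in% names(entries)))
  if (!"category" %in% names(entries)) entries$category <- NA_character_
  entries <- entries %>%
    mutate(
      surface = as.character(.data$surface),
      canonical = trimws(as.character(.data$canonical)),
      key = fold_term(.data$surface)
    ) %>%
    filter(.data$key != "")

  # close canonical terms into the map so normalisation is idempotent
  selfmap <- entries %>%
    distinct(.data$canonical, .data$category) %>%
    mutate(surface = .data$canonical, key = fold_term(.data$canonical))
  lex <- bind_rows(entries, selfmap) %>%
    distinct(.data$key, .data$canonical, .keep_all = TRUE) %>%
    select("key", "surface", "canonical", "category")

  dup <- lex %>% count(.data$key) %>% filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0(
      "conflicting lexicon entries: surface term(s) ",
      paste(sQuote(dup$key), collapse = ", "),
      " map to more than one canonical term"
    ))
  }
  class(lex) <- c("dx_lexicon", class(lex))
  lex
}

#' Read a term lexicon from a TSV file
#'
#' Expects a header with columns `surface`, `canonical` and optionally
#' `category`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A [dx_lexicon()] tibble.
#' @export
load_lexicon <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  dx_lexicon(raw)
}

#' Normalise tokens against a lexicon
#'
#' Looks each token up after whitespace trimming and case folding. Mapped
#' tokens get their canonical term; unmapped tokens are flagged, never
#' silently dropped — downstream ingest decides what to do with them.
#'
#' @param tokens Character vector of raw terms.
#' @param lexicon A [dx_lexicon()].
#' @return A tibble with one row per token: `token` (original), `canonical`
#'   (`NA` when unmapped), `mapped` (logical).
#' @export
normalize_terms <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "dx_lexicon"))
  idx <- match(fold_term(tokens), lexicon$key)
  tibble(
    token = as.character(tokens),
    canonical = lexicon$canonical[idx],
    mapped = !is.na(idx)
  )
}

#' An empty lexicon (everything passes through unmapped)
#' @return A zero-entry [dx_lexicon()].
#' @export
empty_lexicon <- function() dx_lexicon()

fold_term <- function(x) tolower(trimws(as.character(x)))
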