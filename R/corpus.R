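#' Split a free-text symptom string into ordered tokens
#'
#' Clinical symptom strings are entered as comma-separated phrases; splitting
#' on commas (ASCII `,` and fullwidth `，`) is deliberately the only
#' segmentation performed — no dictionary or statistical word segmentation.
#' Tokens are trimmed, empties dropped, and duplicates removed keeping the
#' first occurrence, so the leading positions (which carry the main-symptom
#' convention) are preserved.
#'
#' @param raw_text Character vector of raw symptom strings.
#' @return A list of character vectors, one per input element (a single
#'   string yields a list of length one).
#' @examples
#' segment_symptoms("cough, insomnia, headache")
#' segment_symptoms("cough,,cough , fever")
#' @export
segment_symptoms <- function(raw_text) {
  raw_text[is.na(raw_text)] <- ""
  lapply(strsplit(as.character(raw_text), "[,，]"), function(tok) {
    tok <- trimws(tok)
    tok <- tok[tok != ""]
    tok[!duplicated(tok)]
  })
}

#' Coerce a data frame to a diagnosis-record tibble
#'
#' A record tibble has one row per diagnosed case: a single canonical
#' `disease` label, an ordered list-column `symptoms` of canonical symptom
#' terms (positions 1-3 are the main symptoms), and an opaque `source_id`.
#' Character `symptoms` columns are segmented with [segment_symptoms()].
#'
#' @param x A data frame with columns `disease` and `symptoms` (character,
#'   comma-joined, or a list of character vectors), optional `source_id`.
#' @return A tibble with `disease`, `symptoms` (list-column), `source_id`.
#' @export
as_records <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("disease", "symptoms") %in% names(x)))
  if (!is.list(x$symptoms)) x$symptoms <- segment_symptoms(x$symptoms)
  x$symptoms <- lapply(x$symptoms, function(s) {
    s <- as.character(s)
    s[!duplicated(s)]
  })
  if (!"source_id" %in% names(x)) {
    x$source_id <- sprintf("r%d", seq_len(nrow(x)))
  }
  x %>% select("disease", "symptoms", "source_id")
}

#' Read and clean a diagnosis corpus
#'
#' Reads a record file (TSV with header columns `disease`, `symptoms`,
#' optional `source_id`, or JSON-lines with the same keys), then applies the
#' cleaning conventions: rows whose diagnosis field names more than one
#' disease (comma-separated) are excluded; symptom strings are comma-
#' segmented, deduplicated and normalised against the lexicon; records left
#' with no symptoms are excluded. Every exclusion and every unmapped token
#' is tallied in the ingest report attached to the result.
#'
#' @param path Path to the record file (`.jsonl`/`.ndjson` is read as
#'   JSON-lines, anything else as TSV).
#' @param lexicon A [dx_lexicon()]; defaults to the empty lexicon, under
#'   which every token is unmapped and (with the default policy) kept as-is.
#' @param unmapped Policy for tokens absent from the lexicon:
#'   `"keep_raw"` (default — the raw token becomes a term, since the model
#'   accepts natural-language symptom entry), `"drop_token"`, or
#'   `"drop_record"`.
#' @return A record tibble (see [as_records()]) with an `"ingest_report"`
#'   attribute; retrieve it with [ingest_report()].
#' @export
read_records <- function(path, lexicon = empty_lexicon(),
                         unmapped = c("keep_raw", "drop_token", "drop_record")) {
  unmapped <- arg_match(unmapped)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    raw <- jsonlite::stream_in(file(path), verbose = FALSE) %>% as_tibble()
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  clean_records(raw, lexicon, unmapped)
}

#' @rdname read_records
#' @param raw A raw data frame with `disease` and `symptoms` columns (symptom
#'   field still a comma-joined string or a token list).
#' @export
clean_records <- function(raw, lexicon = empty_lexicon(),
                          unmapped = c("keep_raw", "drop_token", "drop_record")) {
  unmapped <- arg_match(unmapped)
  stopifnot(inherits(lexicon, "dx_lexicon"))
  raw <- as_tibble(raw)

  report <- list(
    rows_in = nrow(raw), malformed = 0L, multi_diagnosis = 0L,
    empty_symptoms = 0L, dropped_record_unmapped = 0L,
    unmapped_tokens = 0L, unmapped_examples = character(), records_out = 0L
  )

  ok <- c("disease", "symptoms") %in% names(raw)
  if (!all(ok)) abort("record input must have columns 'disease' and 'symptoms'")
  bad <- is.na(raw$disease) | trimws(as.character(raw$disease)) == ""
  report$malformed <- sum(bad)
  raw <- raw[!bad, , drop = FALSE]

  # multi-diagnosis rows: a comma in the diagnosis field names >1 disease
  disease_raw <- trimws(as.character(raw$disease))
  multi <- grepl("[,，]", disease_raw)
  report$multi_diagnosis <- sum(multi)
  raw <- raw[!multi, , drop = FALSE]
  disease_raw <- disease_raw[!multi]

  dmap <- normalize_terms(disease_raw, lexicon)
  disease <- ifelse(dmap$mapped, dmap$canonical, disease_raw)

  toks <- if (is.list(raw$symptoms)) {
    lapply(raw$symptoms, function(s) unlist(segment_symptoms(as.character(s))))
  } else {
    segment_symptoms(raw$symptoms)
  }

  drop_rec <- logical(length(toks))
  symptoms <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 0L) {
      symptoms[[i]] <- character()
      next
    }
    m <- normalize_terms(tk, lexicon)
    n_un <- sum(!m$mapped)
    report$unmapped_tokens <- report$unmapped_tokens + n_un
    if (n_un > 0L && length(report$unmapped_examples) < 20L) {
      report$unmapped_examples <-
        head(unique(c(report$unmapped_examples, m$token[!m$mapped])), 20L)
    }
    term <- switch(unmapped,
      keep_raw = ifelse(m$mapped, m$canonical, m$token),
      drop_token = m$canonical[m$mapped],
      drop_record = if (n_un > 0L) character() else m$canonical
    )
    if (unmapped == "drop_record" && n_un > 0L) drop_rec[i] <- TRUE
    symptoms[[i]] <- term[!duplicated(term)]
  }
  report$dropped_record_unmapped <- sum(drop_rec)

  empty <- lengths(symptoms) == 0L & !drop_rec
  report$empty_symptoms <- sum(empty)
  keep <- !drop_rec & !empty

  out <- tibble(
    disease = disease[keep],
    symptoms = symptoms[keep],
    source_id = if ("source_id" %in% names(raw)) {
      as.character(raw$source_id)[keep]
    } else {
      sprintf("r%d", which(keep))
    }
  )
  report$records_out <- nrow(out)
  attr(out, "ingest_report") <- report
  out
}

#' Retrieve the ingest report from a cleaned corpus
#'
#' @param records A record tibble from [read_records()] / [clean_records()].
#' @return A named list of exclusion and unmapped-token counts.
#' @export
ingest_report <- function(records) attr(records, "ingest_report")

#' Write a record tibble to TSV
#'
#' Inverse of [read_records()] for the TSV format: symptoms are re-joined
#' with `", "`.
#'
#' @param records A record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as_records(records)
  out <- tibble(
    disease = records$disease,
    symptoms = map_chr(records$symptoms, paste, collapse = ", "),
    source_id = records$source_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
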