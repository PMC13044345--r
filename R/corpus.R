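# Document / sentence data model, segmentation, serialization, deduplication.

REQUIRED_DOC_FIELDS <- c("doc_id", "patient_id", "doc_type", "text")

#' Controlled vocabulary of clinical document types
#'
#' The nine document categories most frequently encountered in hospital
#' data warehouses, plus a catch-all \code{"Other"}. Any \code{doc_type}
#' outside this vocabulary is coerced to \code{"Other"} on construction.
#'
#' @return Character vector of the ten document-type names.
#' @export
doc_types <- function() {
  c("Nursing care-procedures", "Medical reports",
    "Nursing care-monitoring and vitals",
    "Multidisciplinary follow-up and daily notes", "Imaging reports",
    "Prescriptions and medication orders", "Paramedical care",
    "Administrative and admission", "Results and pathology reports",
    "Other")
}

#' Build a clinical document corpus
#'
#' Assembles per-document vectors into the canonical corpus data frame used
#' throughout the package. Unknown document types are mapped to
#' \code{"Other"}; empty text is rejected.
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param patient_id Character vector of patient identifiers.
#' @param doc_type Character vector of document types (see [doc_types()]).
#' @param text Character vector of raw document text (UTF-8, non-empty).
#' @return A data frame with columns \code{doc_id}, \code{patient_id},
#'   \code{doc_type}, \code{text}.
#' @export
corpus_frame <- function(doc_id, patient_id, doc_type = "Other", text) {
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) {
    stop("doc_id values must be unique within a corpus", call. = FALSE)
  }
  if (any(!nzchar(text))) {
    stop("document text must be non-empty", call. = FALSE)
  }
  doc_type <- as.character(doc_type)
  doc_type[is.na(doc_type) | !(doc_type %in% doc_types())] <- "Other"
  data.frame(doc_id = doc_id, patient_id = as.character(patient_id),
             doc_type = rep_len(doc_type, length(doc_id)),
             text = as.character(text), stringsAsFactors = FALSE)
}

#' Read a line-delimited JSON corpus
#'
#' One JSON object per line with at least the four document fields
#' (\code{doc_id}, \code{patient_id}, \code{doc_type}, \code{text});
#' unknown extra fields are preserved as additional columns.
#'
#' @param path Path to a JSON-lines corpus file.
#' @return Corpus data frame (zero rows for an empty file).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(corpus_frame(character(), character(), character(), character())[0, ])
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop(sprintf("malformed JSON on line %d: %s", i,
                                   conditionMessage(e)), call. = FALSE)
                    })
    missing <- setdiff(REQUIRED_DOC_FIELDS, names(rec))
    if (length(missing) > 0L) {
      stop(sprintf("line %d: missing required field '%s'", i, missing[[1]]),
           call. = FALSE)
    }
    recs[[i]] <- rec
  }
  all_fields <- unique(unlist(lapply(recs, names)))
  all_fields <- c(REQUIRED_DOC_FIELDS, setdiff(all_fields, REQUIRED_DOC_FIELDS))
  cols <- lapply(all_fields, function(f) {
    vapply(recs, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA_character_ else as.character(v)[[1]]
    }, character(1))
  })
  names(cols) <- all_fields
  out <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(out$doc_id)) {
    stop("duplicate doc_id values in corpus file", call. = FALSE)
  }
  out
}

#' Write a corpus as line-delimited JSON
#'
#' Round-trips byte-identically with [read_corpus()] on the four document
#' fields; extra columns are serialized too.
#'
#' @param docs Corpus data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_corpus <- function(docs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(docs) > 0L) {
    for (i in seq_len(nrow(docs))) {
      rec <- as.list(docs[i, , drop = FALSE])
      rec <- lapply(rec, function(v) v[[1]])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con,
                 useBytes = TRUE)
    }
  }
  invisible(path)
}

# Locate sentence-terminator break positions in `text`. A break is the end
# index of (a) a maximal run of [.!?] that is not a protected abbreviation's
# final period, or (b) a newline. Returns sorted integer positions.
find_breaks <- function(text, abbreviations) {
  n <- stringi::stri_length(text)
  runs <- stringi::stri_locate_all_regex(text, "[.!?]+")[[1]]
  breaks <- integer(0)
  if (!is.na(runs[1, 1])) {
    for (r in seq_len(nrow(runs))) {
      s <- runs[r, 1]; e <- runs[r, 2]
      protected <- FALSE
      if (e == s && stringi::stri_sub(text, s, s) == "." &&
          length(abbreviations) > 0L) {
        for (ab in abbreviations) {
          la <- stringi::stri_length(ab)
          if (s - la + 1L >= 1L) {
            cand <- stringi::stri_sub(text, s - la + 1L, s)
            before_ok <- (s - la < 1L) ||
              stringi::stri_detect_regex(
                stringi::stri_sub(text, s - la, s - la), "\\s")
            if (before_ok &&
                stringi::stri_trans_tolower(cand) ==
                stringi::stri_trans_tolower(ab)) {
              protected <- TRUE
              break
            }
          }
        }
      }
      if (!protected) breaks <- c(breaks, e)
    }
  }
  nl <- stringi::stri_locate_all_fixed(text, "\n")[[1]]
  if (!is.na(nl[1, 1])) breaks <- c(breaks, nl[, 1])
  sort(unique(breaks[breaks < n]))  # a break at the last char is implicit
}

#' Segment a clinical document into sentences
#'
#' Deterministic rule-based segmentation: a maximal run of \code{. ! ?}
#' ends a sentence unless the period terminates a protected abbreviation
#' (preceded by start-of-text or whitespace), and a newline always ends a
#' sentence. Spans are 0-based half-open character intervals into the
#' parent text, trimmed of surrounding whitespace, so that the spans are
#' disjoint, ordered, and jointly cover every non-whitespace character
#' exactly once. Sentence ids are \code{doc_id:span_start}, stable across
#' re-runs.
#'
#' @param doc A one-row corpus data frame (or list) with fields
#'   \code{doc_id}, \code{patient_id}, \code{doc_type}, \code{text}.
#' @param abbreviations Character vector of protected tokens ending in a
#'   period (e.g. \code{"M."}, \code{"Dr."}); may be empty.
#' @return Sentence data frame with columns \code{sent_id}, \code{doc_id},
#'   \code{patient_id}, \code{doc_type}, \code{text}, \code{span_start},
#'   \code{span_end}.
#' @export
segment_document <- function(doc, abbreviations = character()) {
  doc <- as.list(doc)
  text <- doc$text[[1]]
  if (is.null(text) || is.na(text) || !nzchar(text)) {
    stop("cannot segment a document with empty text", call. = FALSE)
  }
  n <- stringi::stri_length(text)
  breaks <- find_breaks(text, abbreviations)
  starts_raw <- c(1L, breaks + 1L)
  ends_raw <- c(breaks, n)
  sent_text <- character(0)
  span_start <- integer(0)
  span_end <- integer(0)
  for (i in seq_along(starts_raw)) {
    seg <- stringi::stri_sub(text, starts_raw[[i]], ends_raw[[i]])
    lead <- stringi::stri_locate_first_regex(seg, "\\S")[1, 1]
    if (is.na(lead)) next  # all-whitespace segment
    trail <- stringi::stri_locate_last_regex(seg, "\\S")[1, 1]
    s <- starts_raw[[i]] + lead - 1L
    e <- starts_raw[[i]] + trail - 1L
    sent_text <- c(sent_text, stringi::stri_sub(text, s, e))
    span_start <- c(span_start, s - 1L)  # 0-based
    span_end <- c(span_end, e)           # half-open
  }
  data.frame(
    sent_id = sprintf("%s:%d", doc$doc_id[[1]], span_start),
    doc_id = doc$doc_id[[1]], patient_id = doc$patient_id[[1]],
    doc_type = doc$doc_type[[1]], text = sent_text,
    span_start = span_start, span_end = span_end,
    stringsAsFactors = FALSE)
}

#' Segment every document of a corpus
#'
#' @param docs Corpus data frame.
#' @inheritParams segment_document
#' @return Row-bound sentence data frame across all documents.
#' @export
segment_corpus <- function(docs, abbreviations = character()) {
  if (nrow(docs) == 0L) {
    return(data.frame(sent_id = character(), doc_id = character(),
                      patient_id = character(), doc_type = character(),
                      text = character(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(docs)), function(i) {
    segment_document(docs[i, , drop = FALSE], abbreviations)
  })
  do.call(rbind, out)
}

#' Normalization key for duplicate detection
#'
#' Lowercases, collapses internal whitespace and strips surrounding
#' whitespace. Two sentences with identical keys are treated as duplicates
#' for fold partitioning. Normalization is deliberately minimal (no accent
#' stripping): duplicate removal targets identical sentences.
#'
#' @param text Character vector.
#' @return Character vector of normalized keys.
#' @export
normalize_key <- function(text) {
  stringi::stri_trim_both(
    stringi::stri_replace_all_regex(stringi::stri_trans_tolower(text),
                                    "\\s+", " "))
}

#' Remove duplicated sentences
#'
#' Keeps the first occurrence (input order) of each [normalize_key()]
#' equivalence class. Run before fold partitioning so that no identical
#' sentence can leak between training and validation folds.
#'
#' @param sentences Sentence data frame with a \code{text} column.
#' @return List with \code{sentences} (the unique rows, input order) and
#'   \code{removed_count}.
#' @export
deduplicate <- function(sentences) {
  keys <- normalize_key(sentences$text)
  keep <- !duplicated(keys)
  list(sentences = sentences[keep, , drop = FALSE],
       removed_count = sum(!keep))
}

#' Write a sentence table as line-delimited JSON
#'
#' @param sentences Sentence data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sentences <- function(sentences, path) {
  write_corpus(sentences, path)
}

#' Read a sentence table written by [write_sentences()]
#'
#' @param path Path to a JSON-lines sentence file.
#' @return Sentence data frame.
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(segment_corpus(corpus_frame(character(), character(),
                                       character(), character())[0, ]))
  }
  recs <- lapply(seq_along(lines), function(i) {
    jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
  })
  data.frame(
    sent_id = vapply(recs, function(r) as.character(r$sent_id), character(1)),
    doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
    patient_id = vapply(recs, function(r) as.character(r$patient_id),
                        character(1)),
    doc_type = vapply(recs, function(r) as.character(r$doc_type),
                      character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    span_start = vapply(recs, function(r) as.integer(r$span_start),
                        integer(1)),
    span_end = vapply(recs, function(r) as.integer(r$span_end), integer(1)),
    stringsAsFactors = FALSE)
}
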