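# Rule-based per-condition status classification: keyword matching with
# negation / family-context / cessation / relapse cue scoping at clause level.

#' Valid status labels
#'
#' Per-condition patient status assigned to a sentence. \code{"former"}
#' (condition ceased, used for smoking) is valid only for conditions whose
#' rule set declares it.
#'
#' @return Character vector \code{c("present", "absent", "former", "unknown")}.
#' @export
status_labels <- function() c("present", "absent", "former", "unknown")

#' Construct a per-condition rule set
#'
#' A rule set holds the keyword patterns identifying mentions of one
#' medical condition plus the cue lexica that qualify a mention: negation
#' (condition denied), family context (mention is about a relative),
#' cessation (condition ceased) and relapse (condition resumed, overriding
#' cessation). Cues are scoped to the clause containing the keyword.
#'
#' @param condition Condition name.
#' @param keyword_patterns Non-empty character vector of case-insensitive,
#'   diacritic-sensitive patterns (matched word-bounded).
#' @param negation_cues,family_cues,cessation_cues,relapse_cues Cue lexica
#'   (character vectors, possibly empty).
#' @param clause_delimiters Tokens delimiting clauses; single punctuation
#'   characters or coordinator words.
#' @param family_semantics Either \code{"familial_means_unknown"} (a family
#'   context removes the mention from the patient, e.g. a relative's
#'   diabetes) or \code{"condition_is_familial"} (the condition itself is a
#'   family history, so a family cue is required for an informative label).
#' @param statuses Labels reachable for this condition; \code{"former"}
#'   requires non-empty \code{cessation_cues}.
#' @return An object of class \code{ruleset}.
#' @export
ruleset <- function(condition, keyword_patterns,
                    negation_cues = character(),
                    family_cues = character(),
                    cessation_cues = character(),
                    relapse_cues = character(),
                    clause_delimiters = c(",", ";", ":", "mais", "et"),
                    family_semantics = c("familial_means_unknown",
                                         "condition_is_familial"),
                    statuses = c("present", "absent", "unknown")) {
  if (length(keyword_patterns) == 0L) {
    stop("keyword_patterns must be non-empty", call. = FALSE)
  }
  family_semantics <- match.arg(family_semantics)
  statuses <- match.arg(statuses, status_labels(), several.ok = TRUE)
  if ("former" %in% statuses && length(cessation_cues) == 0L) {
    stop("'former' is reachable only with non-empty cessation_cues",
         call. = FALSE)
  }
  structure(list(condition = condition,
                 keyword_patterns = keyword_patterns,
                 negation_cues = negation_cues,
                 family_cues = family_cues,
                 cessation_cues = cessation_cues,
                 relapse_cues = relapse_cues,
                 clause_delimiters = clause_delimiters,
                 family_semantics = family_semantics,
                 statuses = statuses),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("<ruleset> condition: %s (%s)\n", x$condition,
              paste(x$statuses, collapse = "/")))
  cat(sprintf("  %d keyword pattern(s); cues: %d negation, %d family, %d cessation, %d relapse\n",
              length(x$keyword_patterns), length(x$negation_cues),
              length(x$family_cues), length(x$cessation_cues),
              length(x$relapse_cues)))
  invisible(x)
}

#' Read a rule set from a JSON file
#'
#' @param path Path to a JSON file with the [ruleset()] fields.
#' @return A \code{ruleset}.
#' @export
read_ruleset <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_chr <- function(x) if (is.null(x)) character() else as.character(x)
  ruleset(condition = spec$condition,
          keyword_patterns = as_chr(spec$keyword_patterns),
          negation_cues = as_chr(spec$negation_cues),
          family_cues = as_chr(spec$family_cues),
          cessation_cues = as_chr(spec$cessation_cues),
          relapse_cues = as_chr(spec$relapse_cues),
          clause_delimiters = if (is.null(spec$clause_delimiters))
            c(",", ";", ":", "mais", "et") else as_chr(spec$clause_delimiters),
          family_semantics = spec$family_semantics,
          statuses = as_chr(spec$statuses))
}

#' Load a bundled starter rule set
#'
#' Editable French starter lexica shipped with the package for six
#' conditions. These are reconstructions written for this package, not a
#' published clinical resource; institutions are expected to adapt them.
#'
#' @param condition One of \code{"smoking"}, \code{"diabetes"},
#'   \code{"hypertension"}, \code{"heart_failure"}, \code{"copd"},
#'   \code{"family_cancer"}.
#' @return A \code{ruleset}.
#' @export
default_ruleset <- function(condition = c("smoking", "diabetes",
                                          "hypertension", "heart_failure",
                                          "copd", "family_cancer")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", "rules", paste0(condition, ".json"),
                      package = "medstatus", mustWork = TRUE)
  read_ruleset(path)
}

ci_regex <- function() stringi::stri_opts_regex(case_insensitive = TRUE)

# Word-bounded alternation regex over a lexicon. Entries are themselves
# ICU regular expressions (plain words are their own regex).
lexicon_regex <- function(entries) {
  if (length(entries) == 0L) return(NA_character_)
  paste0("\\b(?:", paste(entries, collapse = "|"), ")\\b")
}

# Clause boundaries: positions of delimiter tokens (single punctuation
# characters matched literally, word tokens matched word-bounded).
clause_of <- function(text, pos, delimiters) {
  n <- stringi::stri_length(text)
  punct <- delimiters[stringi::stri_length(delimiters) == 1L]
  words <- delimiters[stringi::stri_length(delimiters) > 1L]
  parts <- character(0)
  if (length(punct) > 0L) {
    parts <- c(parts, paste0("[", stringi::stri_replace_all_regex(
      paste(punct, collapse = ""), "([\\\\\\]\\[^-])", "\\\\$1"), "]"))
  }
  if (length(words) > 0L) {
    parts <- c(parts, paste0("\\b(?:", paste(words, collapse = "|"), ")\\b"))
  }
  if (length(parts) == 0L) return(c(1L, n))
  locs <- stringi::stri_locate_all_regex(text, paste(parts, collapse = "|"),
                                         opts_regex = ci_regex())[[1]]
  if (is.na(locs[1, 1])) return(c(1L, n))
  starts <- c(1L, locs[, 2] + 1L)
  ends <- c(locs[, 1] - 1L, n)
  i <- max(which(starts <= pos))
  c(starts[[i]], max(ends[[i]], starts[[i]]))
}

# All word-bounded cue hits of one lexicon inside [cs, ce]; returns a data
# frame (cue, cue_type, start, end) in match order, 1-based inclusive spans.
cue_hits <- function(text, lexicon, type, cs, ce) {
  empty <- data.frame(cue = character(), cue_type = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  rx <- lexicon_regex(lexicon)
  if (is.na(rx)) return(empty)
  clause <- stringi::stri_sub(text, cs, ce)
  locs <- stringi::stri_locate_all_regex(clause, rx,
                                         opts_regex = ci_regex())[[1]]
  if (is.na(locs[1, 1])) return(empty)
  data.frame(cue = stringi::stri_sub(clause, locs[, 1], locs[, 2]),
             cue_type = type, start = locs[, 1] + cs - 1L,
             end = locs[, 2] + cs - 1L, stringsAsFactors = FALSE)
}

#' Classify one sentence with a rule set
#'
#' Total function implementing the preannotation decision procedure. With
#' no keyword match the label is \code{unknown}. Otherwise cues are
#' searched in the clause containing the first keyword occurrence, with
#' precedence family > relapse > cessation > negation > bare keyword:
#' \itemize{
#'   \item family cue, \code{familial_means_unknown}: the mention concerns
#'     a relative, label \code{unknown};
#'   \item family cue, \code{condition_is_familial}: the family context is
#'     the condition's required subject; the chain continues (relapse /
#'     cessation / negation / bare). Without a family cue the mention
#'     concerns the patient, not the familial condition: \code{unknown};
#'   \item relapse cue: \code{present} (overrides any cessation cue);
#'   \item cessation cue: \code{former} if declared, else \code{absent};
#'   \item negation cue preceding the keyword in the clause: \code{absent};
#'   \item bare keyword: \code{present}.
#' }
#'
#' @param text A single sentence string.
#' @param rules A [ruleset()].
#' @return A list of class \code{rule_decision}: \code{label},
#'   \code{matched_keyword} (1-based inclusive span or \code{NULL}) and
#'   \code{fired_cues} (audit data frame of keyword and cue hits).
#' @export
classify_with_rules <- function(text, rules) {
  stopifnot(inherits(rules, "ruleset"))
  decision <- function(label, kw = NULL, cues = NULL) {
    structure(list(label = label, matched_keyword = kw,
                   fired_cues = cues), class = "rule_decision")
  }
  kw_rx <- lexicon_regex(rules$keyword_patterns)
  locs <- stringi::stri_locate_all_regex(text, kw_rx,
                                         opts_regex = ci_regex())[[1]]
  if (is.na(locs[1, 1])) return(decision("unknown"))
  kw <- locs[1, ]  # classify on the first occurrence
  fired <- data.frame(
    cue = stringi::stri_sub(text, locs[, 1], locs[, 2]),
    cue_type = "keyword", start = locs[, 1], end = locs[, 2],
    stringsAsFactors = FALSE)
  cl <- clause_of(text, kw[[1]], rules$clause_delimiters)
  fam <- cue_hits(text, rules$family_cues, "family", cl[[1]], cl[[2]])
  rel <- cue_hits(text, rules$relapse_cues, "relapse", cl[[1]], cl[[2]])
  ces <- cue_hits(text, rules$cessation_cues, "cessation", cl[[1]], cl[[2]])
  neg <- cue_hits(text, rules$negation_cues, "negation", cl[[1]], cl[[2]])
  fired <- rbind(fired, fam, rel, ces, neg)
  familial <- rules$family_semantics == "condition_is_familial"
  if (nrow(fam) > 0L && !familial) {
    return(decision("unknown", kw, fired))
  }
  if (familial && nrow(fam) == 0L) {
    # a patient-level mention does not inform the familial condition
    return(decision("unknown", kw, fired))
  }
  label <- if (nrow(rel) > 0L) {
    "present"
  } else if (nrow(ces) > 0L) {
    if ("former" %in% rules$statuses) "former" else "absent"
  } else if (nrow(neg) > 0L && any(neg$start < kw[[1]])) {
    "absent"
  } else {
    "present"
  }
  decision(label, kw, fired)
}

#' @export
print.rule_decision <- function(x, ...) {
  cat(sprintf("<rule_decision> %s", x$label))
  if (!is.null(x$matched_keyword)) {
    cat(sprintf(" (keyword at %d-%d, %d cue hit(s))", x$matched_keyword[[1]],
                x$matched_keyword[[2]],
                sum(x$fired_cues$cue_type != "keyword")))
  }
  cat("\n")
  invisible(x)
}

#' Preannotate a sentence table
#'
#' Applies [classify_with_rules()] to every sentence; order-independent
#' per-sentence decisions with a per-label count summary attached.
#'
#' @param sentences Sentence data frame with \code{sent_id} and \code{text}.
#' @param rules A [ruleset()].
#' @return Data frame \code{sent_id}, \code{condition}, \code{label}, with
#'   attribute \code{"summary"}: named per-label counts over all of
#'   [status_labels()].
#' @export
preannotate <- function(sentences, rules) {
  labels <- vapply(sentences$text, function(t) {
    classify_with_rules(t, rules)$label
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(sent_id = as.character(sentences$sent_id),
                    condition = rep_len(rules$condition, length(labels)),
                    label = labels, stringsAsFactors = FALSE)
  counts <- vapply(status_labels(), function(l) sum(labels == l), integer(1))
  attr(out, "summary") <- counts
  out
}
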