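# Data qualification: unbiased control reservation, preannotation-driven
# filtering, and the bias-assessment distribution statistics.

#' Qualification configuration
#'
#' @param control_fraction Proportion of sentences reserved as an unbiased
#'   control subset, drawn before any preannotation-based decision.
#'   Default 0.10: roughly one sentence in ten is kept unfiltered so that
#'   selection bias introduced by the filter can be quantified.
#' @param unknown_keep_fraction Probability that a sentence preannotated
#'   \code{unknown} survives the filter. Default 0.05, chosen so that at a
#'   realistic pre-filter informative prevalence below 1\% the expected
#'   post-filter prevalence lands in the 5--15\% range.
#' @param seed Integer random seed.
#' @return A list of class \code{qualify_config}.
#' @export
qualify_config <- function(control_fraction = 0.10,
                           unknown_keep_fraction = 0.05, seed = 1L) {
  stopifnot(control_fraction >= 0, control_fraction <= 1,
            unknown_keep_fraction >= 0, unknown_keep_fraction <= 1)
  structure(list(control_fraction = control_fraction,
                 unknown_keep_fraction = unknown_keep_fraction,
                 seed = as.integer(seed)),
            class = "qualify_config")
}

#' Reserve an unbiased control subset
#'
#' Draws \code{round(control_fraction * n)} sentences uniformly without
#' replacement (round half up), before any preannotation-based decision,
#' so the control's status distribution is an unbiased estimate of the
#' corpus distribution. The remainder forms the pool to be filtered.
#'
#' @param sentences Sentence data frame.
#' @param cfg A [qualify_config()].
#' @return List with \code{control} and \code{pool} data frames; their
#'   disjoint union is the input.
#' @export
split_control <- function(sentences, cfg) {
  n <- nrow(sentences)
  n_control <- floor(cfg$control_fraction * n + 0.5)  # round half up
  if (cfg$control_fraction > 0 && n_control < 1L) {
    warning("control_fraction * n < 1; control subset is empty")
  }
  rng <- local_rng(cfg$seed)
  picked <- if (n_control >= 1L) sort(rng$sample(n, n_control)) else integer(0)
  list(control = sentences[picked, , drop = FALSE],
       pool = sentences[setdiff(seq_len(n), picked), , drop = FALSE])
}

# Small seeded RNG scope that leaves the global .Random.seed untouched.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    s
  }
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    expr_fun()
  }
  list(sample = function(n, k) run(function() sample.int(n, k)),
       runif = function(n) run(function() stats::runif(n)),
       rlnorm = function(n, meanlog, sdlog)
         run(function() stats::rlnorm(n, meanlog, sdlog)),
       run = run)
}

#' Filter a sentence pool by its preannotation
#'
#' Every sentence whose preannotated label is informative (anything other
#' than \code{unknown}) is kept; \code{unknown}-preannotated sentences are
#' kept independently with probability \code{unknown_keep_fraction}. Output
#' preserves input order, so the result is deterministic under the seed.
#'
#' @param pool Sentence data frame.
#' @param decisions Preannotation data frame (\code{sent_id}, \code{label}),
#'   as produced by [preannotate()]; must cover every pool sentence.
#' @param cfg A [qualify_config()].
#' @return The filtered sentence data frame.
#' @export
filter_by_preannotation <- function(pool, decisions, cfg) {
  lab <- decisions$label[match(pool$sent_id, decisions$sent_id)]
  if (anyNA(lab)) {
    missing <- pool$sent_id[which(is.na(lab))]
    stop(sprintf("no preannotation decision for sentence(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  rng <- local_rng(cfg$seed + 1L)
  u <- rng$runif(nrow(pool))
  keep <- lab != "unknown" | u < cfg$unknown_keep_fraction
  pool[keep, , drop = FALSE]
}

#' Status-distribution comparison between control and filtered sets
#'
#' For one condition, compares the label distribution of the unfiltered
#' control subset (US) with the preannotation-filtered set (PS). Two
#' statistics are computed per set: the per-status \emph{proportion}
#' \deqn{proportion = c(status) / c(present, absent, former)}
#' over informative statuses only (\code{unknown} excluded from numerator
#' and denominator), and the \emph{prevalence} of informative statuses
#' \deqn{prevalence = c(present, absent, former) /
#'       c(present, absent, former, unknown)}
#' which quantifies how much the filter densified informative content.
#' With zero informative samples the proportions are undefined and
#' reported as \code{NA}, never 0/0.
#'
#' @param us_labels Character vector of gold labels in the control subset.
#' @param ps_labels Character vector of gold labels in the filtered set.
#' @return A list of class \code{distribution_report}: data frame
#'   \code{proportions} (per status, percent) and named numeric
#'   \code{prevalence} (percent) for US and PS.
#' @export
distribution_report <- function(us_labels, ps_labels) {
  informative <- c("present", "absent", "former")
  one_side <- function(labels) {
    cnt <- vapply(c(informative, "unknown"),
                  function(l) sum(labels == l), numeric(1))
    rel <- sum(cnt[informative])
    tot <- sum(cnt)
    prop <- if (rel > 0) 100 * cnt[informative] / rel
            else rep(NA_real_, length(informative))
    prev <- if (tot > 0) 100 * rel / tot else NA_real_
    list(counts = cnt, proportion_pct = prop, prevalence_pct = prev)
  }
  us <- one_side(us_labels)
  ps <- one_side(ps_labels)
  structure(list(
    proportions = data.frame(
      status = informative,
      us_count = as.numeric(us$counts[informative]),
      us_proportion_pct = as.numeric(us$proportion_pct),
      ps_count = as.numeric(ps$counts[informative]),
      ps_proportion_pct = as.numeric(ps$proportion_pct),
      stringsAsFactors = FALSE),
    prevalence = c(us = us$prevalence_pct, ps = ps$prevalence_pct),
    n = c(us = length(us_labels), ps = length(ps_labels))),
    class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat("<distribution_report> status distribution, US vs PS (%)\n")
  df <- x$proportions
  df$us_proportion_pct <- round(df$us_proportion_pct, 1)
  df$ps_proportion_pct <- round(df$ps_proportion_pct, 1)
  print(df, row.names = FALSE)
  cat(sprintf("prevalence of informative statuses: US %.2f%%  PS %.2f%%\n",
              x$prevalence[["us"]], x$prevalence[["ps"]]))
  invisible(x)
}
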