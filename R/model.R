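# Class-weighted multinomial objective and a self-contained linear
# text-classifier backend over hashed word-unigram + character n-gram
# counts; rule-based and external-prediction backends behind the same
# predict contract.

#' Assemble a labeled training dataset
#'
#' Pairs sentences with gold labels, drops duplicated normalized keys
#' (first occurrence kept) and flags classes with fewer than
#' \code{min_per_class} samples as excluded from training and evaluation —
#' statuses too sparse for cross-validation are reported, not scored.
#'
#' @param sentences Sentence data frame.
#' @param labels Character vector of gold labels aligned with
#'   \code{sentences} rows.
#' @param condition Condition name.
#' @param min_per_class Minimum samples per retained class; default 3 so
#'   every class can appear at least once per fold at k = 3.
#' @return Object of class \code{labeled_dataset}: \code{sentences},
#'   \code{labels}, \code{condition}, \code{label_set} (retained classes)
#'   and \code{excluded_classes}.
#' @export
labeled_dataset <- function(sentences, labels, condition = "condition",
                            min_per_class = 3L) {
  stopifnot(nrow(sentences) == length(labels))
  keep <- !duplicated(normalize_key(sentences$text))
  sentences <- sentences[keep, , drop = FALSE]
  labels <- labels[keep]
  cnt <- table(labels)
  label_set <- names(cnt)[cnt >= min_per_class]
  structure(list(sentences = sentences, labels = labels,
                 condition = condition,
                 label_set = sort(label_set),
                 excluded_classes = sort(setdiff(names(cnt), label_set))),
            class = "labeled_dataset")
}

#' Inverse-frequency class weights
#'
#' For class \eqn{c} with \eqn{N_c} of \eqn{N} samples over \eqn{C}
#' classes, \eqn{w_c = N / (C \, N_c)}: each class receives equal
#' aggregate mass \eqn{N_c w_c = N / C}, so the training objective is not
#' dominated by the overwhelming \code{unknown} class.
#'
#' @param labels Character vector of labels (or a \code{labeled_dataset},
#'   in which case its retained classes are used).
#' @return Named numeric vector of weights, one per class.
#' @export
compute_class_weights <- function(labels) {
  if (inherits(labels, "labeled_dataset")) {
    labels <- labels$labels[labels$labels %in% labels$label_set]
  }
  cnt <- table(labels)
  if (any(cnt == 0L)) {
    stop(sprintf("empty class: %s",
                 paste(names(cnt)[cnt == 0L], collapse = ", ")), call. = FALSE)
  }
  n <- sum(cnt)
  c_classes <- length(cnt)
  w <- as.numeric(n / (c_classes * cnt))
  names(w) <- names(cnt)
  w
}

#' Weighted cross-entropy loss
#'
#' \eqn{L = -\sum_i w_{y_i} \log p(y_i \mid x_i)} with natural logarithm.
#' True-class probabilities of zero are clamped at 1e-12 with a warning.
#'
#' @param probs Numeric matrix, one row per sample, columns named by class;
#'   each row must sum to 1 within 1e-9.
#' @param labels True class per row.
#' @param weights Named per-class weights; default all 1.
#' @return The scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels, weights = NULL) {
  stopifnot(is.matrix(probs), nrow(probs) == length(labels))
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("each probability row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(probs)), colnames(probs))
  }
  p <- probs[cbind(seq_along(labels), match(labels, colnames(probs)))]
  if (any(p <= 0)) {
    warning("zero true-class probability clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -sum(weights[labels] * log(p))
}

# ---- feature hashing -------------------------------------------------------

# Deterministic polynomial hash of each string into [0, dim). Factor 131 is
# odd, hence invertible modulo the power-of-two dimension; intermediate
# values stay far below 2^53 so double arithmetic is exact.
hash_strings <- function(strings, dim) {
  cps <- stringi::stri_enc_toutf32(strings)
  vapply(cps, function(cp) {
    h <- 0
    for (v in cp) h <- (h * 131 + v) %% dim
    h
  }, numeric(1)) + 1  # 1-based column index
}

char_ngrams <- function(text, n) {
  len <- stringi::stri_length(text)
  if (len < n) return(character(0))
  stringi::stri_sub(text, seq_len(len - n + 1L),
                    seq_len(len - n + 1L) + n - 1L)
}

#' Hashed n-gram feature matrix
#'
#' Sparse counts of lowercased word unigrams and character n-grams (3--5
#' by default), hashed into a fixed-dimension space (default 2^18).
#' Collisions are accepted: the dimension is fixed so models need no
#' vocabulary file, at the cost of rare feature aliasing.
#'
#' @param texts Character vector of sentences.
#' @param dim Hashing dimension.
#' @param char_n Integer vector of character n-gram orders.
#' @return A \code{dgCMatrix} of \code{length(texts)} rows.
#' @export
hash_features <- function(texts, dim = 2^18, char_n = 3:5) {
  norm <- normalize_key(texts)
  tokens <- stringi::stri_split_regex(norm, "[^\\p{L}\\p{N}']+",
                                      omit_empty = TRUE)
  rows <- integer(0); grams <- character(0)
  per_text <- vector("list", length(norm))
  for (i in seq_along(norm)) {
    g <- c(paste0("w:", tokens[[i]]),
           unlist(lapply(char_n, function(n) {
             paste0("c", n, ":", char_ngrams(norm[[i]], n))
           }), use.names = FALSE))
    per_text[[i]] <- g
  }
  lens <- lengths(per_text)
  grams <- unlist(per_text, use.names = FALSE)
  rows <- rep(seq_along(norm), lens)
  if (length(grams) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(texts), dim)))
  }
  ug <- unique(grams)
  cols <- hash_strings(ug, dim)[match(grams, ug)]
  Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                       dims = c(length(texts), dim))
}

# ---- linear backend --------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the linear extractor backend
#'
#' Multinomial logistic regression over hashed word-unigram + character
#' n-gram counts, minimizing the class-weighted cross-entropy plus an L2
#' penalty by full-batch gradient descent with step halving whenever the
#' loss would increase, so the training loss is non-increasing. Zero
#' initialization and a fixed update order make training deterministic.
#'
#' This backend is a desk-scale, dependency-free stand-in for a fine-tuned
#' transformer encoder: it satisfies the same training and predict
#' contracts so the surrounding pipeline (folding, weighting, evaluation,
#' comparison) is exercised identically.
#'
#' @param dataset A [labeled_dataset()] with at least two retained classes.
#' @param weights Named class weights; default [compute_class_weights()].
#' @param lambda L2 regularization strength (default 1e-4).
#' @param max_iter Iteration cap (default 500).
#' @param lr Initial learning rate (default 2).
#' @param dim,char_n Feature hashing configuration (see [hash_features()]).
#' @param seed Integer seed (training is deterministic regardless; the
#'   seed is recorded for provenance).
#' @return Object of class \code{status_extractor}, backend \code{linear}.
#' @export
train_linear <- function(dataset, weights = NULL, lambda = 1e-4,
                         max_iter = 500L, lr = 2, dim = 2^18,
                         char_n = 3:5, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  keep <- dataset$labels %in% dataset$label_set
  texts <- dataset$sentences$text[keep]
  labels <- dataset$labels[keep]
  classes <- dataset$label_set
  if (length(classes) < 2L) {
    stop("training requires at least two retained classes", call. = FALSE)
  }
  if (is.null(weights)) weights <- compute_class_weights(labels)
  weights <- weights[classes]
  x_full <- hash_features(texts, dim = dim, char_n = char_n)
  # gradient descent only touches hash columns active in the training
  # data; the fitted coefficients are re-embedded in the full hash space
  active <- which(Matrix::colSums(x_full) > 0)
  x <- x_full[, active, drop = FALSE]  # sparse, active columns only
  n <- nrow(x)
  y <- match(labels, classes)
  ymat <- matrix(0, n, length(classes))
  ymat[cbind(seq_len(n), y)] <- 1
  wvec <- weights[y]
  beta <- matrix(0, ncol(x), length(classes))
  b0 <- rep(0, length(classes))
  loss_at <- function(beta, b0) {
    p <- softmax_rows(sweep(as.matrix(x %*% beta), 2, -b0))
    pt <- pmax(p[cbind(seq_len(n), y)], 1e-12)
    -sum(wvec * log(pt)) / n + lambda * sum(beta^2) / 2
  }
  cur <- loss_at(beta, b0)
  trace <- cur
  step <- lr
  for (it in seq_len(max_iter)) {
    p <- softmax_rows(sweep(as.matrix(x %*% beta), 2, -b0))
    resid <- (p - ymat) * wvec
    grad <- as.matrix(Matrix::crossprod(x, resid)) / n + lambda * beta
    grad0 <- colSums(resid) / n
    repeat {
      beta_new <- beta - step * grad
      b0_new <- b0 - step * grad0
      new <- loss_at(beta_new, b0_new)
      if (new <= cur + 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    if (step < 1e-6) break
    improved <- cur - new
    beta <- beta_new; b0 <- b0_new; cur <- new
    trace <- c(trace, cur)
    if (improved < 1e-8 * max(1, abs(cur))) break
  }
  beta_full <- Matrix::sparseMatrix(
    i = rep(active, times = length(classes)),
    j = rep(seq_along(classes), each = length(active)),
    x = as.numeric(beta), dims = c(dim, length(classes)))
  structure(list(backend = "linear", condition = dataset$condition,
                 label_set = classes, beta = beta_full, intercept = b0,
                 dim = dim, char_n = char_n, lambda = lambda,
                 weights = weights, loss_trace = trace, seed = seed),
            class = "status_extractor")
}

#' Rule-based extractor backend
#'
#' Wraps a [ruleset()] behind the common predict contract so rules can be
#' compared with trained backends on identical validation folds.
#'
#' @param rules A [ruleset()].
#' @return Object of class \code{status_extractor}, backend \code{rules}.
#' @export
rules_extractor <- function(rules) {
  stopifnot(inherits(rules, "ruleset"))
  structure(list(backend = "rules", condition = rules$condition,
                 label_set = rules$statuses, rules = rules),
            class = "status_extractor")
}

#' External-prediction extractor backend
#'
#' Stub backend for extractors produced outside this package (a fine-tuned
#' encoder, a prompted generative model): predictions are supplied as a
#' (\code{sent_id}, \code{label}) table, typically read from JSON-lines.
#'
#' @param predictions Data frame with \code{sent_id} and \code{label}.
#' @param condition Condition name.
#' @return Object of class \code{status_extractor}, backend
#'   \code{external}.
#' @export
external_extractor <- function(predictions, condition = "condition") {
  stopifnot(all(c("sent_id", "label") %in% names(predictions)))
  structure(list(backend = "external", condition = condition,
                 label_set = sort(unique(predictions$label)),
                 predictions = predictions),
            class = "status_extractor")
}

#' @export
print.status_extractor <- function(x, ...) {
  cat(sprintf("<status_extractor> backend %s, condition %s, labels: %s\n",
              x$backend, x$condition, paste(x$label_set, collapse = "/")))
  invisible(x)
}

#' Predict status labels for sentences
#'
#' Total and deterministic; labels are restricted to the extractor's label
#' set (the external backend falls back to \code{unknown} for sentences it
#' has no prediction for).
#'
#' @param object A \code{status_extractor}.
#' @param sentences Sentence data frame with \code{sent_id} and
#'   \code{text}.
#' @param ... Unused.
#' @return Data frame (\code{sent_id}, \code{label}).
#' @export
predict.status_extractor <- function(object, sentences, ...) {
  if (nrow(sentences) == 0L) {
    return(data.frame(sent_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  label <- switch(object$backend,
    rules = vapply(sentences$text, function(t) {
      classify_with_rules(t, object$rules)$label
    }, character(1), USE.NAMES = FALSE),
    linear = {
      if (is.null(object$beta)) stop("unfitted extractor", call. = FALSE)
      x <- hash_features(sentences$text, dim = object$dim,
                         char_n = object$char_n)
      z <- sweep(as.matrix(x %*% object$beta), 2, -object$intercept)
      object$label_set[max.col(z, ties.method = "first")]
    },
    external = {
      m <- object$predictions$label[match(sentences$sent_id,
                                          object$predictions$sent_id)]
      m[is.na(m)] <- "unknown"
      m
    },
    stop(sprintf("unknown backend '%s'", object$backend), call. = FALSE))
  data.frame(sent_id = as.character(sentences$sent_id), label = label,
             stringsAsFactors = FALSE)
}

#' Serialize / restore a linear extractor
#'
#' JSON with a header (backend, labels, hashing configuration) and flat
#' weight arrays, so models are plain text and portable.
#'
#' @param extractor A linear \code{status_extractor}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_extractor <- function(extractor, path) {
  stopifnot(extractor$backend == "linear")
  tr <- Matrix::mat2triplet(extractor$beta)
  nz <- tr$x != 0
  obj <- list(backend = "linear", condition = extractor$condition,
              label_set = extractor$label_set, dim = extractor$dim,
              char_n = extractor$char_n, lambda = extractor$lambda,
              intercept = extractor$intercept,
              beta_i = tr$i[nz], beta_j = tr$j[nz], beta_x = tr$x[nz])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_extractor
#' @export
read_extractor <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beta <- Matrix::sparseMatrix(i = obj$beta_i, j = obj$beta_j,
                               x = obj$beta_x,
                               dims = c(obj$dim, length(obj$label_set)))
  structure(list(backend = "linear", condition = obj$condition,
                 label_set = obj$label_set, beta = beta,
                 intercept = obj$intercept, dim = obj$dim,
                 char_n = obj$char_n, lambda = obj$lambda),
            class = "status_extractor")
}
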