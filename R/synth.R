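# Synthetic clinical-corpus generator: sparse informative sentences,
# imbalanced statuses, cue-bearing French templates, document-type mix,
# injected duplicates and patient grouping, with exported gold labels.

# Template banks. "clean" templates are exactly recoverable by the bundled
# rule sets (verified by test); "noisy" templates paraphrase the status
# outside the rule lexica, emulating wordings the rules miss but a trained
# classifier can learn. "family" templates mention the condition in a
# family context (gold unknown for patient-level conditions; for the
# familial condition they are patient-level distractors, also unknown).
# Templates contain no sentence-terminal punctuation and mention exactly
# one condition each. {num} and {year} are filled at generation time.
synth_templates <- function() {
  list(
    smoking = list(
      present = c(
        "Tabagisme actif",
        "Tabagisme évalué à {num} paquets-année",
        "Patient fumeur depuis {year}",
        "Fume environ {num} cigarettes par jour",
        "Consommation de tabac quotidienne",
        "Poursuite du tabagisme malgré les conseils",
        "Patiente fumeuse, un paquet par jour",
        "Reprise du tabac après sevrage en {year}"),
      present_noisy = c(
        "Le patient grille un paquet par jour",
        "Nicotinisme quotidien estimé à un paquet",
        "Consommation de nicotine active",
        "Le patient continue de griller ses clopes"),
      absent = c(
        "Pas de tabagisme",
        "Aucune consommation de tabac",
        "Non fumeur",
        "Patient sans tabac ni alcool",
        "Absence de tabagisme actif",
        "Jamais de tabac"),
      absent_noisy = c(
        "Ne fume pas",
        "Fumeur: non",
        "Tabac zéro depuis toujours",
        "Négation de toute consommation de tabac"),
      former = c(
        "Tabagisme sevré depuis {year}",
        "Ancien fumeur",
        "Arrêt du tabac en {year}",
        "Ex-fumeur depuis {num} ans",
        "Tabagisme stoppé il y a {num} ans",
        "Sevrage tabagique depuis {year}"),
      former_noisy = c(
        "Tabagisme ancien",
        "A fumé par le passé",
        "Fumait autrefois un paquet par jour",
        "Tabac interrompu depuis des années"),
      family = c(
        "Tabagisme chez le père",
        "Mère fumeuse")),
    diabetes = list(
      present = c(
        "Diabète de type 2",
        "Patient diabétique sous metformine",
        "DT2 équilibré sous traitement",
        "Diabète connu depuis {year}",
        "Suivi pour diabète de type 1",
        "Diabète insulinotraité"),
      present_noisy = c(
        "Glycémies chroniquement élevées sous metformine",
        "Hyperglycémie chronique traitée",
        "Trouble glycémique connu de longue date"),
      absent = c(
        "Pas de diabète",
        "Aucun diabète connu",
        "Absence de diabète",
        "Sans diabète",
        "Non diabétique"),
      absent_noisy = c(
        "Diabète formellement écarté",
        "Diabète: non retrouvé",
        "Glycorégulation normale, diabète écarté"),
      family = c(
        "Diabète chez la mère",
        "Père diabétique")),
    hypertension = list(
      present = c(
        "HTA traitée",
        "Hypertension artérielle connue",
        "Patient hypertendu",
        "HTA sous trithérapie depuis {year}",
        "Patiente hypertendue suivie en cardiologie"),
      present_noisy = c(
        "Tension artérielle chroniquement élevée",
        "Chiffres tensionnels élevés sous traitement"),
      absent = c(
        "Pas d'HTA",
        "Absence d'hypertension",
        "Sans HTA connue",
        "Non hypertendu"),
      absent_noisy = c(
        "HTA: non",
        "Profil tensionnel strictement normal",
        "HTA écartée au MAPA"),
      family = c(
        "HTA chez le père",
        "Mère hypertendue")),
    heart_failure = list(
      present = c(
        "Insuffisance cardiaque connue",
        "Décompensation cardiaque récente",
        "Insuffisance cardiaque à FEVG altérée",
        "Hospitalisé pour décompensation cardiaque en {year}"),
      present_noisy = c(
        "Oedèmes et dyspnée sur dysfonction VG",
        "Cardiopathie avec fraction d'éjection effondrée"),
      absent = c(
        "Pas d'insuffisance cardiaque",
        "Absence de décompensation cardiaque",
        "Sans insuffisance cardiaque connue"),
      absent_noisy = c(
        "Insuffisance cardiaque: non",
        "Fonction cardiaque strictement conservée",
        "Insuffisance cardiaque jugée improbable"),
      family = c(
        "Insuffisance cardiaque chez la mère")),
    copd = list(
      present = c(
        "BPCO connue",
        "BPCO stade II",
        "Suivi pneumologique pour BPCO",
        "Bronchopneumopathie chronique obstructive connue"),
      present_noisy = c(
        "Syndrome obstructif sévère aux EFR",
        "Trouble ventilatoire obstructif chronique"),
      absent = c(
        "Pas de BPCO",
        "Absence de BPCO connue"),
      absent_noisy = c(
        "BPCO: non",
        "EFR normales, BPCO écartée"),
      family = c(
        "BPCO chez le père")),
    family_cancer = list(
      present = c(
        "Antécédents familiaux de cancer",
        "Cancer du côlon chez le père",
        "Tumeur du sein chez la mère",
        "Cancer familial connu"),
      present_noisy = c(
        "Plusieurs cas de néoplasie du côlon dans la famille",
        "Terrain carcinologique du côté maternel"),
      absent = c(
        "Pas d'antécédents familiaux de cancer",
        "Aucun cancer familial"),
      absent_noisy = c(
        "Aucun cas de cancer dans la famille"),
      family = c(
        "Cancer de la vessie en cours de traitement",
        "Carcinome urothélial suivi en oncologie")),
    filler = c(
      "Examen clinique sans particularité",
      "Poursuite du traitement habituel",
      "Patient vu ce jour en consultation",
      "Bonne évolution clinique",
      "Surveillance des constantes ce jour",
      "Pansement refait, cicatrice propre",
      "Retour à domicile prévu demain",
      "Bilan biologique en cours",
      "Température à 37 degrés ce matin",
      "Marche dans le couloir sans aide",
      "Alimentation bien tolérée",
      "Nuit calme, patient reposé",
      "Prochaine consultation dans {num} mois",
      "Douleur évaluée à {num} sur 10",
      "Kinésithérapie poursuivie",
      "Transit repris ce jour",
      "Perfusion retirée ce matin",
      "Patient calme et coopérant",
      "Résultats en attente de validation",
      "Avis spécialisé demandé",
      "Traitement antalgique adapté",
      "Sortie validée par le médecin",
      "Constantes stables sur la garde",
      "Hydratation correcte ce jour"))
}

#' Synthetic-corpus configuration
#'
#' Defaults emulate the statistical regime of a hospital data-warehouse
#' corpus: informative sentences are very sparse (per-condition prevalence
#' well below 1\%), statuses within a condition are imbalanced with absent
#' rarer than present, document types follow the skewed mix observed in
#' such warehouses, duplicated sentences occur, and sentences group by
#' patient.
#'
#' @param conditions Named list; per condition a list with
#'   \code{prevalence} (probability a sentence is informative for that
#'   condition), \code{status_probs} (named, over informative statuses,
#'   summing to 1) and \code{family_rate} (probability of a
#'   family-context / distractor sentence, gold \code{unknown}).
#' @param cue_noise Probability an informative sentence uses a paraphrase
#'   outside the rule lexica (default 0: clean-cue regime).
#' @param doc_type_mix Named probabilities over [doc_types()].
#' @param duplicate_rate Probability a sentence re-emits an earlier
#'   sentence's text (fresh id, possibly another patient).
#' @param n_documents,n_patients Corpus size parameters.
#' @param sentences_per_doc Mean sentences per document (1 plus a Poisson
#'   draw).
#' @param seed Integer seed.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(conditions = default_synth_conditions(),
                         cue_noise = 0,
                         doc_type_mix = default_doc_type_mix(),
                         duplicate_rate = 0.05,
                         n_documents = 300L, n_patients = 60L,
                         sentences_per_doc = 8, seed = 1L) {
  stopifnot(cue_noise >= 0, cue_noise <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  total <- sum(vapply(conditions, function(cc)
    cc$prevalence + (cc$family_rate %||% 0), numeric(1)))
  if (total > 1) {
    stop("per-condition prevalences (plus family rates) must sum to <= 1",
         call. = FALSE)
  }
  for (nm in names(conditions)) {
    sp <- conditions[[nm]]$status_probs
    if (abs(sum(sp) - 1) > 1e-8) {
      stop(sprintf("status_probs for '%s' must sum to 1", nm), call. = FALSE)
    }
  }
  structure(list(conditions = conditions, cue_noise = cue_noise,
                 doc_type_mix = doc_type_mix,
                 duplicate_rate = duplicate_rate,
                 n_documents = as.integer(n_documents),
                 n_patients = as.integer(n_patients),
                 sentences_per_doc = sentences_per_doc,
                 seed = as.integer(seed)),
            class = "synth_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default per-condition generative parameters
#'
#' Prevalences reproduce the sub-percent informative density observed in
#' unfiltered clinical sentences; status mixes reproduce the strong
#' class imbalance of annotated corpora (absent much rarer than present
#' for most conditions, former sizeable only for smoking).
#'
#' @return Named list suitable for [synth_config()].
#' @export
default_synth_conditions <- function() {
  list(
    smoking = list(prevalence = 0.0075,
                   status_probs = c(present = 0.507, absent = 0.166,
                                    former = 0.327),
                   family_rate = 0.001),
    diabetes = list(prevalence = 0.0025,
                    status_probs = c(present = 0.874, absent = 0.126),
                    family_rate = 0.001),
    hypertension = list(prevalence = 0.0075,
                        status_probs = c(present = 0.975, absent = 0.025),
                        family_rate = 0.001),
    heart_failure = list(prevalence = 0.0025,
                         status_probs = c(present = 0.458, absent = 0.542),
                         family_rate = 0.001),
    copd = list(prevalence = 0.0017,
                status_probs = c(present = 0.997, absent = 0.003),
                family_rate = 0.001),
    family_cancer = list(prevalence = 0.0005,
                         status_probs = c(present = 0.67, absent = 0.33),
                         family_rate = 0.001))
}

#' Default document-type mix
#'
#' The skewed distribution typical of hospital warehouses: nursing
#' documentation dominates, narrative medical reports are second.
#'
#' @return Named probability vector over [doc_types()].
#' @export
default_doc_type_mix <- function() {
  stats::setNames(c(0.41, 0.23, 0.19, 0.07, 0.04, 0.02, 0.02, 0.01, 0.01,
                    0.00), doc_types())
}

# Cue-free decorations prepended/appended (comma-joined, so they form
# separate clauses and never change the rule decision of the core
# template) to give sentences realistic surface variety; without them a
# template bank of this size would collapse under deduplication.
synth_decorations <- function() {
  list(
    prefix = c("", "", "", "", "vu ce jour", "pour rappel", "à noter",
               "dans les antécédents", "lors du bilan", "au total",
               "selon le dossier", "à l'interrogatoire", "cs du {num}",
               "suivi habituel", "entrée du {num}"),
    suffix = c("", "", "", "", "à réévaluer", "selon le patient",
               "documenté au dossier", "à confirmer", "noté ce jour",
               "cf courrier", "suivi en cours", "dossier mis à jour",
               "vu avec l'interne", "à revoir dans {num} mois"))
}

decorate <- function(core, rng) {
  dec <- synth_decorations()
  pre <- fill_slots(dec$prefix[[rng$sample(length(dec$prefix), 1)]], rng)
  suf <- fill_slots(dec$suffix[[rng$sample(length(dec$suffix), 1)]], rng)
  out <- core
  if (nzchar(pre)) out <- paste0(pre, ", ", out)
  if (nzchar(suf)) out <- paste0(out, ", ", suf)
  out
}

fill_slots <- function(template, rng) {
  if (stringi::stri_detect_fixed(template, "{num}")) {
    template <- stringi::stri_replace_all_fixed(
      template, "{num}", as.character(rng$sample(40, 1)))
  }
  if (stringi::stri_detect_fixed(template, "{year}")) {
    template <- stringi::stri_replace_all_fixed(
      template, "{year}", as.character(1990L + rng$sample(35, 1)))
  }
  template
}

#' Generate a gold-labeled synthetic clinical corpus
#'
#' Draws documents with a patient, a document type and a Poisson number of
#' sentences; each sentence is a duplicate of an earlier one (with
#' probability \code{duplicate_rate}), an informative template for one
#' condition and status (clean or, with probability \code{cue_noise},
#' paraphrased outside the rule lexica), a family-context/distractor
#' template, or a filler. Gold labels are assigned at planting time;
#' bookkeeping counts equal realized gold counts exactly. Deterministic
#' given the seed. Document text joins sentence texts with newlines, so
#' [segment_corpus()] recovers the planted sentences exactly.
#'
#' @param config A [synth_config()].
#' @return Object of class \code{gold_corpus}: \code{documents},
#'   \code{sentences}, \code{gold} (one row per sentence and condition
#'   with a non-\code{unknown}-relevant plant: columns \code{sent_id},
#'   \code{condition}, \code{label}), and \code{bookkeeping} (realized
#'   counts per condition and status, fillers under condition
#'   \code{".filler"}).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rng <- local_rng(config$seed)
  tpl <- synth_templates()
  conds <- names(config$conditions)
  # sentence-category distribution
  cat_names <- c(unlist(lapply(conds, function(cc) paste0(cc, "\r", "inf"))),
                 unlist(lapply(conds, function(cc) paste0(cc, "\r", "fam"))),
                 "filler")
  cat_probs <- c(vapply(conds, function(cc)
                   config$conditions[[cc]]$prevalence, numeric(1)),
                 vapply(conds, function(cc)
                   config$conditions[[cc]]$family_rate %||% 0, numeric(1)))
  cat_probs <- c(cat_probs, 1 - sum(cat_probs))
  type_probs <- config$doc_type_mix[config$doc_type_mix > 0]
  docs <- list(); sents <- list(); gold <- list()
  prev_pool <- list()  # earlier sentences eligible for duplication
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%05d", d)
    patient_id <- sprintf("pat%04d", rng$sample(config$n_patients, 1))
    doc_type <- names(type_probs)[[min(
      findInterval(rng$runif(1), cumsum(type_probs / sum(type_probs))) + 1L,
      length(type_probs))]]
    n_sent <- 1L + rng$run(function()
      stats::rpois(1, max(config$sentences_per_doc - 1, 0)))
    texts <- character(n_sent)
    sent_gold <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      if (length(prev_pool) > 0L &&
          rng$runif(1) < config$duplicate_rate) {
        src <- prev_pool[[rng$sample(length(prev_pool), 1)]]
        texts[[s]] <- src$text
        sent_gold[s] <- list(src$gold)
        next
      }
      u <- rng$runif(1)
      ci <- findInterval(u, cumsum(cat_probs), rightmost.closed = TRUE) + 1L
      cat <- cat_names[[min(ci, length(cat_names))]]
      if (cat == "filler") {
        text <- decorate(
          fill_slots(tpl$filler[[rng$sample(length(tpl$filler), 1)]], rng),
          rng)
        g <- NULL
      } else {
        parts <- stringi::stri_split_fixed(cat, "\r")[[1]]
        cc <- parts[[1]]
        if (parts[[2]] == "fam") {
          bank <- tpl[[cc]]$family
          text <- decorate(fill_slots(bank[[rng$sample(length(bank), 1)]],
                                      rng), rng)
          g <- data.frame(condition = cc, label = "unknown",
                          stringsAsFactors = FALSE)
        } else {
          sp <- config$conditions[[cc]]$status_probs
          status <- names(sp)[[min(
            findInterval(rng$runif(1), cumsum(sp / sum(sp))) + 1L,
            length(sp))]]
          noisy <- rng$runif(1) < config$cue_noise
          bank_name <- if (noisy) paste0(status, "_noisy") else status
          bank <- tpl[[cc]][[bank_name]]
          if (is.null(bank)) bank <- tpl[[cc]][[status]]
          text <- decorate(fill_slots(bank[[rng$sample(length(bank), 1)]],
                                      rng), rng)
          g <- data.frame(condition = cc, label = status,
                          stringsAsFactors = FALSE)
        }
      }
      texts[[s]] <- text
      sent_gold[s] <- list(g)  # keeps NULL slots (filler) in place
      prev_pool[[length(prev_pool) + 1L]] <- list(text = text, gold = g)
    }
    doc_text <- paste(texts, collapse = "\n")
    starts0 <- c(0L, utils::head(cumsum(stringi::stri_length(texts) + 1L),
                                 -1L))
    sent_ids <- paste0(doc_id, ":", starts0)
    docs[[d]] <- data.frame(doc_id = doc_id, patient_id = patient_id,
                            doc_type = doc_type, text = doc_text,
                            stringsAsFactors = FALSE)
    sents[[d]] <- data.frame(
      sent_id = sent_ids, doc_id = doc_id, patient_id = patient_id,
      doc_type = doc_type, text = texts, span_start = starts0,
      span_end = starts0 + stringi::stri_length(texts),
      stringsAsFactors = FALSE)
    for (s in seq_len(n_sent)) {
      if (!is.null(sent_gold[[s]])) {
        gold[[length(gold) + 1L]] <- cbind(
          data.frame(sent_id = sent_ids[[s]], stringsAsFactors = FALSE),
          sent_gold[[s]])
      }
    }
  }
  documents <- do.call(rbind, docs)
  sentences <- do.call(rbind, sents)
  gold <- if (length(gold) > 0L) do.call(rbind, gold) else
    data.frame(sent_id = character(), condition = character(),
               label = character(), stringsAsFactors = FALSE)
  book <- list()
  for (cc in conds) {
    g <- gold[gold$condition == cc, , drop = FALSE]
    for (st in status_labels()) {
      n_st <- if (st == "unknown") {
        nrow(sentences) - sum(g$label != "unknown")
      } else {
        sum(g$label == st)
      }
      book[[length(book) + 1L]] <- data.frame(
        condition = cc, status = st, count = n_st, stringsAsFactors = FALSE)
    }
  }
  book[[length(book) + 1L]] <- data.frame(
    condition = ".filler", status = "unknown",
    count = nrow(sentences) - length(unique(gold$sent_id)),
    stringsAsFactors = FALSE)
  structure(list(documents = documents, sentences = sentences, gold = gold,
                 bookkeeping = do.call(rbind, book), config = config),
            class = "gold_corpus")
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat(sprintf("<gold_corpus> %d documents, %d sentences, %d patients, seed %d\n",
              nrow(x$documents), nrow(x$sentences),
              length(unique(x$documents$patient_id)), x$config$seed))
  inf <- x$gold[x$gold$label != "unknown", , drop = FALSE]
  cat(sprintf("  informative plants: %d (%.2f%%)\n", nrow(inf),
              100 * nrow(inf) / nrow(x$sentences)))
  invisible(x)
}

#' Gold labels of one condition over all sentences
#'
#' @param corpus A [generate_corpus()] result.
#' @param condition Condition name.
#' @return Character vector aligned with \code{corpus$sentences}: the
#'   planted label, \code{unknown} for unplanted sentences.
#' @export
gold_labels <- function(corpus, condition) {
  g <- corpus$gold[corpus$gold$condition == condition, , drop = FALSE]
  lab <- g$label[match(corpus$sentences$sent_id, g$sent_id)]
  lab[is.na(lab)] <- "unknown"
  lab
}

#' Simulate two annotators over a gold corpus
#'
#' Annotator A returns the gold labels; annotator B flips each label with
#' the given probability to a label drawn uniformly from the other
#' declared statuses. Durations are lognormal, with uninformative
#' (\code{unknown}) sentences dismissed faster than informative ones.
#'
#' @param corpus A [generate_corpus()] result.
#' @param condition Condition name.
#' @param disagreement_rate Flip probability in [0, 1).
#' @param statuses Label universe for flips.
#' @param duration_means Named means (seconds): \code{unknown} and
#'   \code{informative}; defaults 1.5 and 3.0.
#' @param sdlog Lognormal shape parameter (default 0.5).
#' @param seed Integer seed.
#' @return List of two annotation record tables, \code{a} and \code{b}.
#' @export
simulate_annotators <- function(corpus, condition, disagreement_rate = 0,
                                statuses = c("present", "absent", "former",
                                             "unknown"),
                                duration_means = c(unknown = 1.5,
                                                   informative = 3.0),
                                sdlog = 0.5, seed = 1L) {
  stopifnot(disagreement_rate >= 0, disagreement_rate < 1)
  gold <- gold_labels(corpus, condition)
  n <- length(gold)
  rng <- local_rng(seed)
  flip <- rng$runif(n) < disagreement_rate
  b_lab <- gold
  if (any(flip)) {
    for (i in which(flip)) {
      others <- setdiff(statuses, gold[[i]])
      b_lab[[i]] <- others[[rng$sample(length(others), 1)]]
    }
  }
  meanlog <- log(duration_means) - sdlog^2 / 2
  draw_durations <- function(labels) {
    m <- ifelse(labels == "unknown", meanlog[["unknown"]],
                meanlog[["informative"]])
    rng$rlnorm(length(labels), m, sdlog)
  }
  ids <- corpus$sentences$sent_id
  list(a = annotation_records(ids, "annotA", condition, gold,
                              draw_durations(gold)),
       b = annotation_records(ids, "annotB", condition, b_lab,
                              draw_durations(b_lab)))
}
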