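---
title: "Sentence-level medical status extraction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentence-level medical status extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and its formulation

Clinical data warehouses hold large volumes of unstructured notes in which
a patient's status with respect to a condition — smoking, diabetes,
hypertension, heart failure, COPD, family history of cancer — is expressed
at the sentence level, entangled with negation ("pas de diabète"), family
context ("diabète chez la mère"), and temporality ("sevrage en 2020,
reprise récente"). Named-entity approaches find the condition term but
miss these cues. This package instead frames extraction as *sentence
classification*: each sentence receives exactly one status per condition,
from

* **present** — the patient has the condition,
* **absent** — the condition is explicitly denied,
* **former** — the condition ceased (declared only for smoking),
* **unknown** — the sentence carries no usable status information.

The package implements the complete annotation-efficient workflow around
that formulation: deterministic segmentation, rule-based preannotation,
density-aware corpus qualification, kappa-gated annotation management,
class-weighted training of a self-contained linear classifier,
deduplicated stratified cross-validation, and an iterative refinement
loop. A synthetic French clinical-corpus generator with exported gold
labels makes every stage testable offline.

## Rule engine semantics

A `ruleset()` holds keyword patterns for one condition plus four cue
lexica. Classification of a sentence proceeds:

1. no keyword match → `unknown`;
2. otherwise cues are searched in the **clause** containing the first
   keyword (clauses are maximal runs between `, ; :` and the coordinators
   *mais*/*et*), with precedence
   family > relapse > cessation > negation > bare keyword;
3. a relapse cue ("reprise") yields `present` even when a cessation cue
   ("sevrage") is also in scope — a relapse after cessation means an
   active condition;
4. a cessation cue yields `former` where declared, `absent` otherwise;
5. a negation cue *preceding* the keyword in its clause yields `absent`;
6. a bare keyword yields `present`.

Clause-level scoping is deliberate: negations attach locally ("des atcd
cardio, HTA, DT2 non traité" — the *non* belongs to the treatment
clause), and a clause window is the simplest rule whose behaviour can be
audited from the `fired_cues` trail each decision carries.

**Family semantics.** Two regimes exist. For patient-level conditions
(`familial_means_unknown`) a family cue in scope voids the mention: the
relative's diabetes says nothing about the patient. For the familial
condition itself (`condition_is_familial`, family history of cancer) we
made the opposite design choice: the family cue is the *required subject*
of the condition. A keyword without a family cue (the patient's own
cancer) is `unknown`; with a family cue the precedence chain continues,
so "Pas d'antécédents familiaux de cancer" correctly yields `absent`.
Treating any family cue as a terminal `present` would misclassify
explicitly negated family histories, which are precisely the informative
`absent` mentions for this condition.

The shipped lexica (`inst/extdata/rules/*.json`) are starter
reconstructions written for this package, matched case-insensitively but
diacritic-sensitively ("fumé" is not "fume": stripping accents would
create false cue hits more often than it would recover real ones). They
are editable config files, not a clinical resource.

## Qualification and the bias statistics

Informative sentences are very sparse in warehouse corpora (well below
1% before filtering). Qualification first reserves an *unfiltered
control subset* (default `control_fraction = 0.10`, drawn per sentence
before any preannotation-based decision, size rounded half-up), then
keeps every sentence preannotated informative while retaining
`unknown`-preannotated ones only with probability
`unknown_keep_fraction`. The default 0.05 was chosen once so that, at a
realistic sub-percent prevalence \(p\), the expected post-filter
prevalence \(p / (p + (1-p) \cdot 0.05)\) lands in the 5–15% range; at
\(p = 0.0075\) it is about 14%, a better-than-tenfold densification.

Two statistics quantify the selection bias this introduces, compared
between the control (US) and filtered (PS) sets:

\[
\text{proportion}(s) = \frac{c(s)}{c(\text{present},\text{absent},\text{former})},
\qquad
\text{prevalence} = \frac{c(\text{present},\text{absent},\text{former})}
     {c(\text{present},\text{absent},\text{former},\text{unknown})}
\]

The proportion excludes `unknown` from numerator and denominator — the
filter's entire purpose is to remove `unknown`, so including it would
mask distributional shifts among the informative statuses. With zero
informative samples the proportions are reported not-applicable, never
0/0.

## Agreement gating

Two annotators label a common subset (default 10% of each batch, at
least 20 sentences) and agreement is measured by Cohen's kappa,
\(\kappa = (P_o - P_e)/(1 - P_e)\), with \(P_o\) the observed agreement
and \(P_e = \sum_l m_A(l)\, m_B(l)\) the chance agreement from the label
marginals. The gate passes at \(\kappa \ge 0.8\) (boundary inclusive).
When both annotators are degenerate on one label, \(P_e = 1\) and the
formula is undefined; we define \(\kappa = 1\) if \(P_o = 1\) and 0
otherwise, a convention that arises with small fixtures. A failing gate
triggers disagreement analysis: ambiguous terms are collected in a
`correction_plan()`, the sentences containing them are re-annotated, the
replaced records are archived with the guideline version, and kappa is
recomputed. One revision round is applied per iteration call; if the
gate still fails a warning asks for an extended term list rather than
looping silently.

## Class-weighted training objective

Annotated status data is heavily imbalanced (`unknown` dominates;
`absent` is typically much rarer than `present`). Training minimizes the
class-weighted cross-entropy

\[
L = -\sum_i w_{y_i} \log p(y_i \mid x_i),
\qquad w_c = \frac{N}{C\,N_c},
\]

so each of the \(C\) classes contributes equal aggregate mass
\(N_c w_c = N/C\). The bundled backend is a multinomial logistic model
over hashed features — lowercased word unigrams plus character 3–5-grams,
hashed into \(2^{18}\) dimensions by a polynomial-131 hash. Collisions
are accepted: a fixed dimension means models need no vocabulary file,
and at desk scale aliasing is rare. Optimization is full-batch gradient
descent (initial step 2, L2 penalty \(10^{-4}\), cap 500 iterations)
with step halving whenever the loss would increase, so the training loss
is non-increasing and, with zero initialization, training is fully
deterministic. True-class probabilities are floored at \(10^{-12}\)
(with a warning) before the logarithm.

This backend is a desk-scale stand-in for a fine-tuned transformer
encoder: it satisfies the same training and predict contracts, so
folding, weighting, evaluation and comparison are exercised identically.
Predictions from an actual fine-tuned or prompted model can be injected
through the `external_extractor()` stub and compared on the same folds.
Classes with fewer than `min_per_class = 3` gold samples are excluded
from training and scoring (three allows at least one sample per fold at
\(k = 3\)); they are reported as excluded, mirroring how sparse statuses
must be handled rather than silently scored.

## Evaluation

Metrics are one-vs-rest per status: precision, recall, specificity, and
F-score, with the aggregates

\[
\text{BA} = \frac{1}{C} \sum_c \frac{\text{recall}_c + \text{specificity}_c}{2},
\qquad
F_{\text{macro}} = \frac{1}{C} \sum_c F_1(c),
\]

averaged over the *evaluated statuses* only — classes with at least one
gold sample in the validation fold, with `unknown` always included. Any
0/0 ratio is reported not-applicable and excluded from aggregates with a
flag; a status without support is never scored 0. The document-type
breakdown applies the same convention per (type, status) cell. Because
the evaluated-status set is explicit, both aggregate conventions (same
set for BA and macro F, or different sets) are computable.

Cross-validation uses stratified folds built after deduplication on a
minimal normalized key (lowercase, collapsed whitespace — no accent
stripping, since only *identical* sentences leak): items are shuffled
within class under the seed and dealt round-robin with a pointer that
continues across classes, which bounds the per-class and overall fold
size spread by one. A class with fewer than \(k\) samples is a
contract error naming the class — the caller drops it via
`min_per_class`. This precondition intentionally excludes leave-one-out
folding, which cannot be stratified; requests with \(k\) above the
smallest class count fail loudly instead of degrading. Fold SDs are
sample standard deviations (\(n-1\)); the optional backend comparison is
a two-sided paired t-test on per-fold macro F (\(k-1\) df). Because
partitioning is by sentence, not patient, `audit_patient_overlap()`
reports the fraction of validation sentences whose patient also appears
in training.

## The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` draws documents (patient, document type, Poisson
sentence count) whose sentences are French status templates, family
context/distractor templates, or fillers, with duplicates re-emitting
earlier sentences under fresh ids and possibly other patients. Defaults
state the regime the pipeline targets:

| parameter | default | rationale |
|---|---|---|
| per-condition prevalence | 0.0005–0.0075 | sub-percent informative density of unfiltered warehouse sentences |
| status mix | e.g. smoking 0.507/0.166/0.327 | strong imbalance, absent ≪ present, former sizeable only for smoking |
| doc-type mix | 0.41/0.23/0.19/… | skewed warehouse mix dominated by nursing documentation |
| `cue_noise` | 0 | clean-cue regime; raise to emulate out-of-lexicon wordings |
| `duplicate_rate` | 0.05 | boilerplate repetition across notes |
| `sentences_per_doc` | 8 | short clinical notes |
| `n_documents`, `n_patients` | 300, 60 | several documents per patient so folds share patients |

Every *clean* template is exactly recoverable by the shipped rules (a
test asserts this), so at `cue_noise = 0` rule classification attains
macro F 1.0 and preannotation counts equal the generator's bookkeeping —
which in turn equals realized gold counts exactly. *Noisy* templates
paraphrase the status outside the rule lexica ("Ne fume pas", "Tabac
zéro"), so rules degrade with noise while a trained classifier, having
seen such wordings with labels, does not — the qualitative pattern that
motivates training at all. Cue-free decorations (comma-joined prefixes
and suffixes, forming separate clauses that cannot change the rule
decision) give sentences surface variety; without them the bank would
collapse under deduplication.

A green test on this corpus establishes that the pipeline machinery is
correct under the stated statistical regime. It does *not* establish
clinical performance: the generator has template-level vocabulary
diversity only, no misspellings, no section structure, no multi-condition
sentences (unless enabled), and its noisy wordings are a closed set. The
generator plants one condition mention per sentence, keeping gold labels
unambiguous.

Simulated annotators wrap the gold labels: annotator A returns them;
annotator B flips each with a given rate to a uniformly random other
declared status; durations are lognormal (sdlog 0.5) with `unknown`
sentences faster (mean 1.5 s) than informative ones (3.0 s), emulating
the quick dismissal of uninformative sentences.

## The iterative loop

`run_iteration()` chains segmentation → preannotation → qualification →
gated annotation → accumulation → cross-validation of the trained
backend against the rule baseline on identical folds. Two invariants are
enforced by construction: the cumulative dataset only grows, and human
(or simulated-human) labels are the only training labels — preannotations
are never gold. The trained extractor replaces the rule preannotator for
the next iteration only if it beats the rules on the same folds.
`should_stop()` stops at mean macro F ≥ 0.90 (configurable) or at the
iteration cap, with a warning in the latter case. Per-step wall-clock
and counts are logged in each iteration report; timing is
hardware-dependent and deliberately not part of any test.

## Numerical and convention summary

* control subset size: round half-up; drawn before any
  preannotation-based decision.
* duplicate key: lowercase + whitespace collapse only.
* kappa at \(P_e = 1\): 1 if \(P_o = 1\), else 0.
* undefined metric ratios: `NA`, excluded from aggregates, flagged.
* probability floor in the loss: \(10^{-12}\), with a warning.
* hashing: polynomial (factor 131) into \(2^{18}\); intermediate values
  stay below \(2^{53}\), so double arithmetic is exact.
* gradient descent: zero init, step halving on loss increase, stop when
  the relative improvement falls below \(10^{-8}\) or the step below
  \(10^{-6}\).
* fold SD: sample (\(n-1\)).
* all randomness flows through per-call seeded generators that leave the
  global RNG state untouched.

## Known limitations

Rule scoping is clause-local: cues separated from the keyword by a
clause delimiter are out of scope even when a human would attach them
("Tabac: non"). Hypothetical or uncertain mentions ("suspicion de
BPCO") default to whatever the cue chain yields — typically `present` —
because distinguishing them needs guideline-level annotation decisions
outside the rule engine. Fold partitioning is by sentence; patient-level
leakage is audited, not prevented. The linear backend's feature space is
bag-of-n-grams: long-range temporal constructions are represented only
through their local wording.
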