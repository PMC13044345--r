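{
  "condition": "family_cancer",
  "comment": "Starter French lexicon written for this package; a reconstruction to be adapted locally, not a published clinical resource. The condition itself is familial: a family cue is required for an informative label.",
  "keyword_patterns": ["cancer", "cancers", "néoplasie", "tumeur", "carcinome", "K"],
  "negation_cues": ["pas de", "pas d'", "absence de", "absence d'", "aucun", "aucune", "sans", "non", "nie", "jamais", "ni"],
  "family_cues": ["familial", "familiale", "familiaux", "antécédents familiaux", "père", "mère", "frère", "soeur", "sœur", "parents", "grand-père", "grand-mère", "oncle", "tante"],
  "cessation_cues": [],
  "relapse_cues": [],
  "clause_delimiters": [",", ";", ":", "mais", "et"],
  "family_semantics": "condition_is_familial",
  "statuses": ["present", "absent", "unknown"]
}
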