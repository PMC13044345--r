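{
  "condition": "diabetes",
  "comment": "Starter French lexicon written for this package; a reconstruction to be adapted locally, not a published clinical resource.",
  "keyword_patterns": ["diabète", "diabétique", "DT2", "DT1", "DNID", "DID", "diabete"],
  "negation_cues": ["pas de", "pas d'", "absence de", "absence d'", "aucun", "aucune", "sans", "non", "nie", "jamais", "ni"],
  "family_cues": ["familial", "familiale", "familiaux", "père", "mère", "frère", "soeur", "sœur", "parents", "grand-père", "grand-mère"],
  "cessation_cues": [],
  "relapse_cues": [],
  "clause_delimiters": [",", ";", ":", "mais", "et"],
  "family_semantics": "familial_means_unknown",
  "statuses": ["present", "absent", "unknown"]
}
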