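{
  "condition": "smoking",
  "comment": "Starter French lexicon written for this package; a reconstruction to be adapted locally, not a published clinical resource.",
  "keyword_patterns": ["tabac", "tabagisme", "tabagique", "fumeur", "fumeuse", "fume", "cigarettes?", "paquets-année", "PA"],
  "negation_cues": ["pas de", "pas d'", "absence de", "absence d'", "aucun", "aucune", "sans", "non", "nie", "jamais", "ni", "0", "zéro"],
  "family_cues": ["familial", "familiale", "familiaux", "père", "mère", "frère", "soeur", "sœur", "parents", "grand-père", "grand-mère"],
  "cessation_cues": ["sevré", "sevrée", "sevrage", "arrêt", "arrêté", "arrêtée", "stoppé", "stoppée", "ancien fumeur", "ancienne fumeuse", "ex-fumeur", "ex-fumeuse", "ancien tabagisme"],
  "relapse_cues": ["reprise", "repris", "rechute", "récidive"],
  "clause_delimiters": [",", ";", ":", "mais", "et"],
  "family_semantics": "familial_means_unknown",
  "statuses": ["present", "absent", "former", "unknown"]
}
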