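# Search-engine export dialect registry.
#
# Each dialect maps the engine's protein-level CSV columns onto the four
# canonical fields (protein, spectral_count, score, molecular_weight).
# Detection is by case-insensitive presence of every `columns` value in the
# header row. `score_best` says which direction is a better score when
# duplicate identifiers are merged (GPM's log(e) is better when more
# negative). Signatures are representative of each engine's documented
# protein export; engines change export formats across versions, so edit or
# extend this file rather than the code.
gpm_xtandem:
  label: "X!Tandem / Global Proteome Machine"
  columns:
    protein: "identifier"
    spectral_count: "total"
    score: "log(e)"
    molecular_weight: "mr"
  score_best: min
metamorpheus:
  label: "MetaMorpheus"
  columns:
    protein: "protein accession"
    spectral_count: "number of psms"
    score: "protein score"
    molecular_weight: "molecular weight"
  score_best: max
proteome_discoverer:
  label: "Proteome Discoverer"
  columns:
    protein: "accession"
    spectral_count: "# psms"
    score: "score"
    molecular_weight: "mw [kda]"
  score_best: max
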