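{
  "schema_version": 1,
  "description": "Multiplicative scoring constants. score = string_similarity * status_multiplier. string_similarity = 1 for an exact match, otherwise the product of per-feature penalties. All values lie in (0, 1].",
  "penalties": {
    "separator_mismatch": 0.999,
    "cap_flip": 0.998,
    "cap_mixed": 0.995,
    "plural": 0.98,
    "unaligned": 0.9
  },
  "status_multipliers": {
    "standard_name": 1.0,
    "curated": 0.9966,
    "synonym": 0.99,
    "former_name": 0.85
  }
}
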