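{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "screenkit pipeline report",
  "type": "object",
  "required": ["meta", "cell_ledger", "guide_qc", "enrichment",
               "pseudotime_shift", "geneset_ztest"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "alpha", "n_iter", "clusters"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "alpha": {"type": "number"},
        "n_iter": {"type": "integer"},
        "clusters": {"type": "array", "items": {"type": "string"}}
      }
    },
    "cell_ledger": {
      "type": "object",
      "required": ["input", "hash_singlets", "mito_filter",
                   "guide_detected", "cluster_filter"],
      "additionalProperties": {"type": "integer"}
    },
    "guide_qc": {
      "type": "object",
      "required": ["nt_background", "nt_removed", "retained_guides"]
    },
    "late_gene_set": {"type": "array", "items": {"type": "string"}},
    "enrichment": {"type": "array"},
    "pseudotime_shift": {"type": "array"},
    "geneset_ztest": {"type": "array"}
  }
}
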