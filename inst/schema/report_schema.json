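{
  "description": "Structural schema for scatacpipe summary reports",
  "required": {
    "stages_run": "array",
    "aggregate_qc": "list",
    "clusters": "list",
    "n_peaks": "number",
    "differential": "list",
    "motifs": "list",
    "tss_enrichment_score": "number"
  }
}
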