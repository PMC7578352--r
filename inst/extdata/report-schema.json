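{
  "required": {
    "ensembles": {
      "required": {
        "wt": {
          "required": {
            "n_models": "number",
            "mean_contact_count": "number"
          }
        },
        "mut": {
          "required": {
            "n_models": "number",
            "mean_contact_count": "number"
          }
        }
      }
    },
    "n_pairs": "number",
    "n_annotated": "number",
    "net_change": {
      "required": {
        "all": "number",
        "annotated": "number",
        "per_interface": "array"
      }
    },
    "annotated_pairs": "array",
    "config": {
      "required": {
        "cutoff": "number",
        "min_seq_sep": "number",
        "k": "number",
        "threshold": "number"
      }
    },
    "provenance": {
      "required": {
        "package": "string",
        "version": "string"
      }
    }
  }
}
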