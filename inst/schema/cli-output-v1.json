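{
  "id": "chartsize/cli-output",
  "version": 1,
  "description": "Envelope for every chartsize CLI JSON payload.",
  "fields": {
    "schema": "string of the form chartsize/<subcommand>/<version>",
    "result": "array of row objects; numeric fields carry full precision"
  },
  "subcommands": {
    "categorical": ["n", "p", "expected_count", "detection_prob", "halfwidth", "ci_lower", "ci_upper"],
    "continuous": ["n", "mu", "sigma", "cv", "halfwidth", "relative_halfwidth"],
    "cv-estimate": ["label", "cv", "n_obs", "mean", "sd", "zeros_excluded", "log_transformed"],
    "grid": ["n", "p", "expected_count", "detection_prob", "halfwidth", "ci_lower", "ci_upper"],
    "curve": ["cv", "n"],
    "simulate": ["mode", "estimate", "mc_se", "replicates", "seed", "closed_form", "flagged"]
  }
}
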