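{
  "schema_version": "1.0",
  "metric_names": ["max_force_bipolar", "bleeding_rate", "tip_distance_mean", "acceleration_bipolar"],
  "categories": ["safety", "safety", "movement", "movement"],
  "weights": [-0.6002, -0.5106, -1.4902, -0.271],
  "bias": 0,
  "normalization": {
    "means": [0, 0, 0, 0],
    "sds": [1, 1, 1, 1]
  },
  "class_encoding": {"skilled": 1, "novice": -1},
  "training_meta": {
    "note": "Published weights of the validated 4-metric subpial-resection model. Training-cohort normalization parameters and bias were not published; identity normalization is synthetic (model consumes z-scores directly) and the bias is set to 0."
  }
}
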