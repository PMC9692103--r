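{
  "rules": {
    "entropy_sqi": {
      "boundaries": [
        {"op": "<", "value": 5.0, "decision": "reject"}
      ],
      "na_decision": "reject"
    },
    "kurtosis_sqi": {
      "boundaries": [
        {"op": ">", "value": 6.0, "decision": "reject"}
      ],
      "na_decision": "reject"
    },
    "msq_sqi": {
      "boundaries": [
        {"op": "<", "value": 0.8, "decision": "reject"}
      ],
      "na_decision": "reject"
    },
    "ectopic_sqi": {
      "boundaries": [
        {"op": ">", "value": 0.2, "decision": "reject"}
      ],
      "na_decision": "reject"
    },
    "corr_prom_1": {
      "boundaries": [
        {"op": "<", "value": 0.3, "decision": "reject"}
      ],
      "na_decision": "reject"
    }
  },
  "order": ["entropy_sqi", "kurtosis_sqi", "msq_sqi", "ectopic_sqi", "corr_prom_1"]
}
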