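{
  "name": "buprenorphine_full",
  "drug": "buprenorphine",
  "scale": "full",
  "dose_units": "ug/kg/day",
  "note": "Dose magnitudes (start/max/steps/floor) are placeholder simulation values, not clinically validated; indicator thresholds are the scale's decision-rule cutoffs.",
  "start_dose": 5.3,
  "max_dose": 15.0,
  "thresholds": [
    {
      "name": "i",
      "metric": "avg24",
      "comparator": "<",
      "threshold": 8
    },
    {
      "name": "ii",
      "metric": "avg24",
      "comparator": "<=",
      "threshold": 8
    },
    {
      "name": "iii",
      "metric": "sum3",
      "comparator": "<",
      "threshold": 18
    },
    {
      "name": "iv",
      "metric": "sum3",
      "comparator": ">=",
      "threshold": 24
    },
    {
      "name": "v",
      "metric": "sum3",
      "comparator": ">=",
      "threshold": 28
    },
    {
      "name": "vi",
      "metric": "single_score",
      "comparator": ">=",
      "threshold": 12
    }
  ],
  "rules": [
    {
      "name": "discontinue",
      "indicator": "iii",
      "guards": [
        "treating",
        "had_first_decrease",
        "48h_since_increase",
        "24h_since_decrease"
      ],
      "action": "discontinue",
      "priority": 60,
      "dose_at_most": 2.7
    },
    {
      "name": "wean",
      "indicator": "i",
      "guards": [
        "treating",
        "48h_since_increase",
        "24h_since_decrease"
      ],
      "action": "decrease",
      "dose_delta": {
        "kind": "relative",
        "value": -0.1
      },
      "priority": 50
    },
    {
      "name": "escalate_large",
      "indicator": "v",
      "guards": [
        "treating"
      ],
      "action": "increase",
      "dose_delta": {
        "kind": "absolute",
        "value": 2.6
      },
      "priority": 45
    },
    {
      "name": "escalate",
      "indicator": "iv",
      "guards": [
        "treating"
      ],
      "action": "increase",
      "dose_delta": {
        "kind": "absolute",
        "value": 1.3
      },
      "priority": 40
    },
    {
      "name": "rescue",
      "indicator": "vi",
      "guards": [
        "treating"
      ],
      "action": "rescue",
      "dose_delta": {
        "kind": "absolute",
        "value": 1.8
      },
      "priority": 30
    },
    {
      "name": "initiate",
      "indicator": "vi",
      "guards": [
        "not_yet_treating"
      ],
      "action": "initiate",
      "priority": 10
    }
  ]
}
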