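{
  "name": "morphine_short",
  "drug": "morphine",
  "scale": "short",
  "dose_units": "mg/kg/day",
  "note": "Dose magnitudes (start/max/steps/floor) are placeholder simulation values, not clinically validated; indicator thresholds are the scale's decision-rule cutoffs.",
  "start_dose": 0.4,
  "max_dose": 1.2,
  "thresholds": [
    {
      "name": "i",
      "metric": "avg24",
      "comparator": "<",
      "threshold": 4.6
    },
    {
      "name": "ii",
      "metric": "avg24",
      "comparator": "<=",
      "threshold": 4.6
    },
    {
      "name": "iii",
      "metric": "sum3",
      "comparator": "<=",
      "threshold": 10
    },
    {
      "name": "iv",
      "metric": "sum3",
      "comparator": ">=",
      "threshold": 14
    },
    {
      "name": "v",
      "metric": "sum3",
      "comparator": ">=",
      "threshold": 16
    },
    {
      "name": "vi",
      "metric": "single_score",
      "comparator": ">=",
      "threshold": 7
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
      "dose_at_most": 0.2
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
        "value": 0.1
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
        "value": 0.05
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
        "value": 0.08
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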