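{
  "format": "fctbn-model/1",
  "nodes": ["TBI", "BaPa", "PTSD", "Depr", "SuAb"],
  "parents": {
    "TBI": ["BaPa", "PTSD", "Depr", "SuAb"],
    "BaPa": ["TBI", "PTSD", "Depr", "SuAb"],
    "PTSD": ["TBI", "BaPa", "Depr", "SuAb"],
    "Depr": ["TBI", "BaPa", "PTSD", "SuAb"],
    "SuAb": ["TBI", "BaPa", "PTSD", "Depr"]
  },
  "max_parents": 4,
  "progressive": false,
  "m": 1,
  "covariates": "age_score",
  "coefficients": {
    "TBI": {
      "01": [
        {
          ".baseline": -2.2,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": -0.3,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ],
      "10": [
        {
          ".baseline": -1.9,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ]
    },
    "BaPa": {
      "01": [
        {
          ".baseline": -1.6,
          "TBI": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0.4,
          "TBI": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ],
      "10": [
        {
          ".baseline": -1.9,
          "TBI": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0,
          "TBI": 0,
          "PTSD": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ]
    },
    "PTSD": {
      "01": [
        {
          ".baseline": -2.5,
          "TBI": 1.1,
          "BaPa": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0.2,
          "TBI": 0,
          "BaPa": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ],
      "10": [
        {
          ".baseline": -1.9,
          "TBI": 0,
          "BaPa": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0,
          "TBI": 0,
          "BaPa": 0,
          "Depr": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ]
    },
    "Depr": {
      "01": [
        {
          ".baseline": -2.3,
          "TBI": 0.7,
          "BaPa": 0.6,
          "PTSD": 0.9,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0.3,
          "TBI": 0.2,
          "BaPa": 0,
          "PTSD": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ],
      "10": [
        {
          ".baseline": -1.9,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": 0,
          "SuAb": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": 0,
          "SuAb": 0,
          "_row": "age_score"
        }
      ]
    },
    "SuAb": {
      "01": [
        {
          ".baseline": -2.6,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": 1,
          "Depr": 0.8,
          "_row": "(Intercept)"
        },
        {
          ".baseline": -0.2,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": -0.2,
          "Depr": 0,
          "_row": "age_score"
        }
      ],
      "10": [
        {
          ".baseline": -1.9,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "_row": "(Intercept)"
        },
        {
          ".baseline": 0,
          "TBI": 0,
          "BaPa": 0,
          "PTSD": 0,
          "Depr": 0,
          "_row": "age_score"
        }
      ]
    }
  }
}
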