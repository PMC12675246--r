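{
  "levels": {
    "dimensions": {
      "labels": ["physiological", "psychological", "external"],
      "experts": [
        [
          [1, 4, 7],
          [0.25, 1, 2],
          [0.142857142857143, 0.5, 1]
        ],
        [
          [1, 5, 7],
          [0.2, 1, 2],
          [0.142857142857143, 0.5, 1]
        ],
        [
          [1, 4, 7],
          [0.25, 1, 1],
          [0.142857142857143, 1, 1]
        ]
      ]
    },
    "physiological": {
      "labels": ["musculoskeletal_deterioration", "activity_radius", "self_care"],
      "experts": [
        [
          [1, 3, 0.5],
          [0.333333333333333, 1, 0.2],
          [2, 5, 1]
        ],
        [
          [1, 4, 0.5],
          [0.25, 1, 0.2],
          [2, 5, 1]
        ],
        [
          [1, 3, 0.5],
          [0.333333333333333, 1, 0.166666666666667],
          [2, 6, 1]
        ]
      ]
    },
    "self_care": {
      "labels": ["postural_transition", "ambulation", "toileting", "dressing", "feeding", "bathing", "grooming"],
      "experts": [
        [
          [1, 1, 1, 2, 1, 1, 2],
          [1, 1, 1, 2, 1, 1, 2],
          [1, 1, 1, 2, 1, 1, 2],
          [0.5, 0.5, 0.5, 1, 0.5, 0.5, 1],
          [1, 1, 1, 2, 1, 1, 2],
          [1, 1, 1, 2, 1, 1, 2],
          [0.5, 0.5, 0.5, 1, 0.5, 0.5, 1]
        ],
        [
          [1, 2, 1, 3, 1, 2, 2],
          [0.5, 1, 2, 2, 2, 1, 3],
          [1, 0.5, 1, 3, 1, 2, 2],
          [0.333333333333333, 0.5, 0.333333333333333, 1, 1, 0.5, 2],
          [1, 0.5, 1, 1, 1, 2, 2],
          [0.5, 1, 0.5, 2, 0.5, 1, 3],
          [0.5, 0.333333333333333, 0.5, 0.5, 0.5, 0.333333333333333, 1]
        ],
        [
          [1, 1, 0.5, 2, 0.5, 1, 1],
          [1, 1, 1, 1, 1, 0.5, 2],
          [2, 1, 1, 2, 0.5, 1, 1],
          [0.5, 1, 0.5, 1, 0.5, 0.333333333333333, 1],
          [2, 1, 2, 2, 1, 1, 1],
          [1, 2, 1, 3, 1, 1, 2],
          [1, 0.5, 1, 1, 1, 0.5, 1]
        ]
      ]
    },
    "psychological": {
      "labels": ["sports_anxiety", "social_engagement", "self_efficacy"],
      "experts": [
        [
          [1, 2, 3],
          [0.5, 1, 2],
          [0.333333333333333, 0.5, 1]
        ],
        [
          [1, 3, 3],
          [0.333333333333333, 1, 2],
          [0.333333333333333, 0.5, 1]
        ],
        [
          [1, 2, 3],
          [0.5, 1, 1],
          [0.333333333333333, 1, 1]
        ]
      ]
    },
    "external": {
      "labels": ["familial_support", "financial_capacity"],
      "experts": [
        [
          [1, 3],
          [0.333333333333333, 1]
        ],
        [
          [1, 4],
          [0.25, 1]
        ],
        [
          [1, 3],
          [0.333333333333333, 1]
        ]
      ]
    }
  },
  "note": "SYNTHETIC fixture data: pairwise-comparison matrices constructed from the published weight structure as stand-ins for the study's expert panel judgments, which are not publicly deposited. Not survey data."
}
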