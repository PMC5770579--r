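{
  "version": "assist-v3.0-default-1",
  "comment": "Item weights and skip table for the ASSIST screening instrument. Weights follow the instrument's V3.0 conventions; edit this file to use a site-specific variant. Item 1 (lifetime use) is boolean and never contributes to the involvement score. Items 6 and 7 are asked even when past-3-month use is 'never'; tobacco omits item 5.",
  "substances": [
    "tobacco",
    "alcohol",
    "cannabis",
    "cocaine",
    "amphetamine_type_stimulants",
    "inhalants",
    "sedatives",
    "hallucinogens",
    "opioids",
    "other"
  ],
  "substance_labels": {
    "tobacco": "Tobacco products",
    "alcohol": "Alcoholic beverages",
    "cannabis": "Cannabis",
    "cocaine": "Cocaine",
    "amphetamine_type_stimulants": "Amphetamine-type stimulants",
    "inhalants": "Inhalants",
    "sedatives": "Sedatives or sleeping pills",
    "hallucinogens": "Hallucinogens",
    "opioids": "Opioids",
    "other": "Other drugs"
  },
  "items": {
    "1": {
      "text": "Have you ever used this substance?",
      "codes": [0, 1],
      "weights": [0, 0],
      "contributes": false
    },
    "2": {
      "text": "In the past 3 months, how often have you used it?",
      "codes": [0, 1, 2, 3, 4],
      "weights": [0, 2, 3, 4, 6],
      "contributes": true
    },
    "3": {
      "text": "How often have you had a strong desire or urge to use?",
      "codes": [0, 1, 2, 3, 4],
      "weights": [0, 3, 4, 5, 6],
      "contributes": true
    },
    "4": {
      "text": "How often has use led to health, social, legal, or financial problems?",
      "codes": [0, 1, 2, 3, 4],
      "weights": [0, 4, 5, 6, 7],
      "contributes": true
    },
    "5": {
      "text": "How often have you failed to do what was normally expected because of use?",
      "codes": [0, 1, 2, 3, 4],
      "weights": [0, 5, 6, 7, 8],
      "contributes": true
    },
    "6": {
      "text": "Has a friend, relative, or anyone else expressed concern about your use?",
      "codes": [0, 1, 2],
      "weights": [0, 6, 3],
      "contributes": true
    },
    "7": {
      "text": "Have you tried and failed to control, cut down, or stop using?",
      "codes": [0, 1, 2],
      "weights": [0, 6, 3],
      "contributes": true
    }
  },
  "items_excluded": {
    "tobacco": [5]
  },
  "skip": {
    "lifetime_never_skips": [2, 3, 4, 5, 6, 7],
    "recent_never_skips": [3, 4, 5]
  },
  "risk_cutoffs": {
    "low_max": 3,
    "moderate_max": 26
  },
  "score_max": 39
}
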