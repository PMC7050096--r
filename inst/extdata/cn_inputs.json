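{
  "country": "CN",
  "discount_rate": 0.03,
  "exchange_rate_cny_per_usd": 6.7,
  "prevalence": {
    "lt1": 0.3287,
    "pd1_1_49": 0.3218,
    "ge50": 0.3495
  },
  "prop_subsequent": {
    "combo": {
      "value": 0.542,
      "low": 0.4336,
      "high": 0.6504
    },
    "chemo": {
      "value": 0.565,
      "low": 0.452,
      "high": 0.678
    }
  },
  "induction_cycles": 4,
  "pembrolizumab_max_cycles": 35,
  "subsequent_mix": {
    "combo": {
      "docetaxel": 1,
      "nivolumab": 0,
      "pembrolizumab": 0
    },
    "chemo": {
      "docetaxel": 0,
      "nivolumab": 0,
      "pembrolizumab": 1
    }
  },
  "subsequent_max_cycles": {
    "docetaxel": "Inf",
    "nivolumab": 35,
    "pembrolizumab": 35
  },
  "platinum_mix": {
    "carboplatin": 0.5,
    "cisplatin": 0.5
  },
  "carboplatin_dose_mg": 750,
  "premedication_cost_per_cycle": 0,
  "ae_incidence": {
    "combo": {
      "thrombocytopenia": 0.079,
      "neutropenia": 0.158,
      "anemia": 0.163
    },
    "chemo": {
      "thrombocytopenia": 0.067,
      "neutropenia": 0.119,
      "anemia": 0.153
    }
  },
  "wtp": 27351,
  "body": {
    "bsa_m2": 1.72,
    "weight_kg": 65
  },
  "price_per_mg": {
    "pembrolizumab": {
      "value": 26.74,
      "low": 21.4,
      "high": 32.1
    },
    "pemetrexed": {
      "value": 3.12,
      "low": 2.5,
      "high": 3.7
    },
    "carboplatin": {
      "value": 0.16,
      "low": 0.13,
      "high": 0.19
    },
    "cisplatin": {
      "value": 0.23,
      "low": 0.18,
      "high": 0.27
    },
    "nivolumab": {
      "value": 13.82,
      "low": 11.1,
      "high": 16.6
    },
    "docetaxel": {
      "value": 10.6,
      "low": 8.5,
      "high": 12.7
    }
  },
  "monitoring_cost": {
    "value": 102.5,
    "low": 82,
    "high": 123
  },
  "pdl1_test_cost": {
    "value": 48.5,
    "low": 38.8,
    "high": 58.2
  },
  "subsequent_cost": {
    "docetaxel": {
      "value": 1364,
      "low": 1092,
      "high": 1638
    },
    "nivolumab": {
      "value": 2689,
      "low": 21518,
      "high": 32278
    },
    "pembrolizumab": {
      "value": 5337,
      "low": 4270,
      "high": 6404
    }
  },
  "supportive_cost": {
    "value": 338,
    "low": 159,
    "high": 476
  },
  "ae_cost": {
    "thrombocytopenia": {
      "value": 6397,
      "low": 5117,
      "high": 7676
    },
    "neutropenia": {
      "value": 466,
      "low": 415,
      "high": 508
    },
    "anemia": {
      "value": 537,
      "low": 478,
      "high": 585
    }
  },
  "utilities": {
    "pfs": {
      "value": 0.804,
      "low": 0.536,
      "high": 0.883
    },
    "pd": {
      "value": 0.321,
      "low": 0.05,
      "high": 0.473
    }
  },
  "donation_program": true
}
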