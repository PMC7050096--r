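{
  "country": "US",
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
  "wtp": 100000,
  "body": {
    "bsa_m2": 1.84,
    "weight_kg": 71.4
  },
  "price_per_mg": {
    "pembrolizumab": {
      "value": 48.987,
      "low": 39.2,
      "high": 58.8
    },
    "pemetrexed": {
      "value": 6.8107,
      "low": 5.45,
      "high": 8.17
    },
    "carboplatin": {
      "value": 0.06504,
      "low": 0.052,
      "high": 0.078
    },
    "cisplatin": {
      "value": 0.1847,
      "low": 0.15,
      "high": 0.22
    },
    "nivolumab": {
      "value": 27.498,
      "low": 22,
      "high": 33
    },
    "docetaxel": {
      "value": 1.345,
      "low": 1.1,
      "high": 1.6
    }
  },
  "monitoring_cost": {
    "value": 732,
    "low": 586,
    "high": 878
  },
  "pdl1_test_cost": {
    "value": 60,
    "low": 48,
    "high": 72
  },
  "subsequent_cost": {
    "docetaxel": {
      "value": 185.6,
      "low": 148,
      "high": 223
    },
    "nivolumab": {
      "value": 8835,
      "low": 7068,
      "high": 10602
    },
    "pembrolizumab": {
      "value": 9797,
      "low": 7838,
      "high": 11756
    }
  },
  "supportive_cost": {
    "value": 3472,
    "low": 2778,
    "high": 4166
  },
  "ae_cost": {
    "thrombocytopenia": {
      "value": 1814,
      "low": 1451,
      "high": 2177
    },
    "neutropenia": {
      "value": 1043,
      "low": 834,
      "high": 1251
    },
    "anemia": {
      "value": 1654,
      "low": 1323,
      "high": 1985
    }
  },
  "utilities": {
    "pfs": {
      "value": 0.652,
      "low": 0.431,
      "high": 0.833
    },
    "pd": {
      "value": 0.47,
      "low": 0.184,
      "high": 0.773
    }
  },
  "donation_program": false
}
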