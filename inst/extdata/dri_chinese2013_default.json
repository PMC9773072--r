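[
  {
    "nutrient": "carbohydrate",
    "age_min_months": 37,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 120
  },
  {
    "nutrient": "protein",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 20
  },
  {
    "nutrient": "protein",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 25
  },
  {
    "nutrient": "calcium",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 500
  },
  {
    "nutrient": "calcium",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 650
  },
  {
    "nutrient": "iron",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 6
  },
  {
    "nutrient": "iron",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 7
  },
  {
    "nutrient": "zinc",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 3.2
  },
  {
    "nutrient": "zinc",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 4.6
  },
  {
    "nutrient": "iodine",
    "age_min_months": 37,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 65
  },
  {
    "nutrient": "potassium",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "AI",
    "threshold": 900
  },
  {
    "nutrient": "potassium",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "AI",
    "threshold": 1200
  },
  {
    "nutrient": "vitamin_a",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 220
  },
  {
    "nutrient": "vitamin_a",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 260
  },
  {
    "nutrient": "vitamin_b1",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 0.5
  },
  {
    "nutrient": "vitamin_b1",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 0.6
  },
  {
    "nutrient": "vitamin_b2",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 0.5
  },
  {
    "nutrient": "vitamin_b2",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 0.6
  },
  {
    "nutrient": "vitamin_b3",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 5
  },
  {
    "nutrient": "vitamin_b3",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 6
  },
  {
    "nutrient": "vitamin_b6",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 0.5
  },
  {
    "nutrient": "vitamin_b6",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 0.6
  },
  {
    "nutrient": "vitamin_b9",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 130
  },
  {
    "nutrient": "vitamin_b9",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 150
  },
  {
    "nutrient": "vitamin_b12",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 0.8
  },
  {
    "nutrient": "vitamin_b12",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 1
  },
  {
    "nutrient": "vitamin_c",
    "age_min_months": 37,
    "age_max_months": 49,
    "rule_type": "EAR",
    "threshold": 35
  },
  {
    "nutrient": "vitamin_c",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 40
  },
  {
    "nutrient": "vitamin_d",
    "age_min_months": 37,
    "age_max_months": 73,
    "rule_type": "EAR",
    "threshold": 8
  },
  {
    "nutrient": "fiber_density",
    "age_min_months": 37,
    "age_max_months": 73,
    "rule_type": "FIBER_DENSITY",
    "threshold": 10
  },
  {
    "nutrient": "fat_energy_pct",
    "age_min_months": 49,
    "age_max_months": 73,
    "rule_type": "AMDR_UPPER",
    "threshold": 35
  }
]
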