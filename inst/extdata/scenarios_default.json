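[
  {"model_id": 1, "mode": "SUBSTITUTE", "substitute_food_id": "soymilk",
   "label": "model 1 (soymilk substitution)"},
  {"model_id": 2, "mode": "SUBSTITUTE", "substitute_food_id": "cow_milk",
   "label": "model 2 (cow's milk substitution)"},
  {"model_id": 3, "mode": "SUBSTITUTE", "substitute_food_id": "fmp_psc",
   "label": "model 3 (FMP-PSC substitution)"},
  {"model_id": 4, "mode": "TOPUP", "substitute_food_id": "cow_milk",
   "target_amount": 350, "label": "model 4 (cow's milk top-up)"},
  {"model_id": 5, "mode": "TOPUP", "substitute_food_id": "fmp_psc",
   "target_amount": 350, "label": "model 5 (FMP-PSC top-up)"}
]
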