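{
  "id": "toy_model_synthetic",
  "description": "Synthetic test network with an analytically solvable optimum; not a reconstruction of any organism.",
  "metabolites": [
    {"id": "A_e", "formula": "C6H12O6"},
    {"id": "A_c", "formula": "C6H12O6"},
    {"id": "B_c", "formula": "C3H4O3"},
    {"id": "B_e", "formula": "C3H4O3"},
    {"id": "h2_c", "formula": "H2"},
    {"id": "co2_c", "formula": "CO2"},
    {"id": "h2o_c", "formula": "H2O"}
  ],
  "reactions": [
    {"id": "EX_A_e", "metabolites": {"A_e": -1}, "lower_bound": -10, "upper_bound": 0},
    {"id": "T_A", "metabolites": {"A_e": -1, "A_c": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R1", "metabolites": {"A_c": -1, "B_c": 2, "h2_c": 2}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "R3", "metabolites": {"B_c": -1, "h2o_c": -3, "co2_c": 3, "h2_c": 5}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "T_B", "metabolites": {"B_c": -1, "B_e": 1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "EX_B_e", "metabolites": {"B_e": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "EX_co2_c", "metabolites": {"co2_c": -1}, "lower_bound": 0, "upper_bound": 1000},
    {"id": "EX_h2o_c", "metabolites": {"h2o_c": -1}, "lower_bound": -1000, "upper_bound": 1000}
  ]
}
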