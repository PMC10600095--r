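{
  "harvest": 9500000,
  "woodfuel_replacement": 0.4,
  "hwp_window": 50,
  "study_window": 28,
  "convention": {
    "moisture_green": 0.5,
    "carbon_dry": 0.5,
    "co2_per_c": 3.66666666666667,
    "tc_per_m3": 0.28,
    "gt_per_m3_product": 1.4
  },
  "substitution": {
    "timber_per_wall": 0.0175,
    "timber_density_20mc": 500,
    "concrete_wall_ef": 10,
    "gas_ef": 0.066,
    "wood_energy_yield": 9000,
    "energy_sector": "gas_energy",
    "minerals_sector": "minerals"
  },
  "estate": {
    "area": 710000,
    "rotation_baseline": 50,
    "rotation_extended": 54,
    "yield_class": 16,
    "soil": {
      "half_life": 30,
      "turnover": 0.015,
      "residue_frac": 0.3
    },
    "green_t_per_m3": 1
  },
  "afforestation": {
    "planting_rate": 20000,
    "start_year": 2023,
    "end_year": 2050,
    "mix": [
      {
        "fraction": 0.5,
        "yield_class": 16,
        "label": "commercial_conifer"
      },
      {
        "fraction": 0.5,
        "yield_class": 9.66666666666667,
        "label": "conifer_broadleaf_mix"
      }
    ]
  }
}
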