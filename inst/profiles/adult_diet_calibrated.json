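{
  "description": "Adult dietary profile that reproduces the published hazard-quotient table for the Andalusian urban-garden survey. RfDs in mg/kg-bw/day; the Pb (2e-3) and Mo (5e-3) values and all ingestion rates were back-calculated from the published HQ table (see calibrate_ingestion_rate). Ingestion rates in kg fresh weight/day. Regional geochemical backgrounds are user input and deliberately absent.",
  "elements": {
    "As": {"rfd": 3e-4, "slope_factor": 1.5, "trigger_value": 36},
    "B":  {"rfd": 0.2},
    "Ba": {"rfd": 0.2},
    "Cd": {"rfd": 1e-3,
           "food_limits": {"leafy": 0.20, "bulbous": 0.05, "fruiting": 0.05}},
    "Co": {"rfd": 3e-4},
    "Cr": {"rfd": 3e-3, "trigger_value": 10000},
    "Cu": {"rfd": 0.04, "trigger_value": 595},
    "Mo": {"rfd": 5e-3},
    "Ni": {"rfd": 0.02, "trigger_value": 1540},
    "Pb": {"rfd": 2e-3, "trigger_value": 275,
           "food_limits": {"leafy": 0.3, "bulbous": 0.1, "fruiting": 0.05}},
    "Zn": {"rfd": 0.3, "trigger_value": 10000}
  },
  "exposure": {
    "ir_fresh": {
      "chard": 4.94e-3,
      "onion": 1.825e-2,
      "tomato": 2.49e-2,
      "zucchini": 5.60e-3,
      "eggplant": 5.09e-3,
      "lettuce": 1.054e-2,
      "pepper": 6.63e-3
    },
    "bw": 70,
    "ef": 365,
    "ed": 30,
    "at_nc": 10950,
    "at_c": 28470,
    "fw_factor": 0.085
  }
}
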