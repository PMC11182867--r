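{
  "description": "Adult dietary profile with the literature oral reference doses as stated in the survey text: Pb 3.5e-3 mg/kg-bw/day and no value for Mo. Does not include ingestion rates (supply your own or use calibrate_ingestion_rate).",
  "elements": {
    "As": {"rfd": 3e-4, "slope_factor": 1.5, "trigger_value": 36},
    "B":  {"rfd": 0.2},
    "Ba": {"rfd": 0.2},
    "Cd": {"rfd": 1e-3,
           "food_limits": {"leafy": 0.20, "bulbous": 0.05, "fruiting": 0.05}},
    "Co": {"rfd": 3e-4},
    "Cr": {"rfd": 3e-3, "trigger_value": 10000},
    "Cu": {"rfd": 0.04, "trigger_value": 595},
    "Mo": {},
    "Ni": {"rfd": 0.02, "trigger_value": 1540},
    "Pb": {"rfd": 3.5e-3, "trigger_value": 275,
           "food_limits": {"leafy": 0.3, "bulbous": 0.1, "fruiting": 0.05}},
    "Zn": {"rfd": 0.3, "trigger_value": 10000}
  },
  "exposure": {
    "bw": 70,
    "ef": 365,
    "ed": 30,
    "at_nc": 10950,
    "at_c": 28470,
    "fw_factor": 0.085
  }
}
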