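{
  "name": "synthetic reduced glucose network (illustrative stoichiometry)",
  "M_biomass": 0.966,
  "g_lim": 12.3,
  "biomass": {
    "c_model": {
      "protein": 0.50, "lipid": 0.08, "polysacch": 0.22,
      "RNA": 0.11, "DNA": 0.01, "storage": 0.08
    }
  },
  "species": [
    {"id": "glc_e",     "carbon": 6,  "mass_g_mmol": 0.180, "dfG": -915.0,  "exchanged": true},
    {"id": "o2_e",      "carbon": 0,  "mass_g_mmol": 0.032, "dfG": 16.4,    "exchanged": true},
    {"id": "co2_e",     "carbon": 1,  "mass_g_mmol": 0.044, "dfG": -386.0,  "exchanged": true},
    {"id": "etoh_e",    "carbon": 2,  "mass_g_mmol": 0.046, "dfG": -181.0,  "exchanged": true},
    {"id": "glc",       "carbon": 6,  "mass_g_mmol": 0.180, "dfG": -915.0,  "exchanged": false},
    {"id": "pyr",       "carbon": 3,  "mass_g_mmol": 0.088, "dfG": -640.0,  "exchanged": false},
    {"id": "atp",       "carbon": 10, "mass_g_mmol": 0.507, "dfG": -1360.0, "exchanged": false},
    {"id": "adp",       "carbon": 10, "mass_g_mmol": 0.427, "dfG": -1400.0, "exchanged": false},
    {"id": "nadh",      "carbon": 21, "mass_g_mmol": 0.665, "dfG": -1000.0, "exchanged": false},
    {"id": "nad",       "carbon": 21, "mass_g_mmol": 0.664, "dfG": -1100.0, "exchanged": false},
    {"id": "protein",   "carbon": 6,  "mass_g_mmol": 0.140, "dfG": -1150.0,  "exchanged": false},
    {"id": "lipid",     "carbon": 12, "mass_g_mmol": 0.220, "dfG": -2900.0, "exchanged": false},
    {"id": "polysacch", "carbon": 6,  "mass_g_mmol": 0.162, "dfG": -900.0,  "exchanged": false},
    {"id": "RNA",       "carbon": 9,  "mass_g_mmol": 0.320, "dfG": -1160.0, "exchanged": false},
    {"id": "DNA",       "carbon": 9,  "mass_g_mmol": 0.310, "dfG": -1220.0, "exchanged": false},
    {"id": "storage",   "carbon": 6,  "mass_g_mmol": 0.162, "dfG": -900.0,  "exchanged": false},
    {"id": "biomass",   "carbon": 36.06, "mass_g_mmol": 0.889, "dfG": -7029.4, "exchanged": true}
  ],
  "reactions": [
    {"id": "EX_glc",  "stoich": {"glc_e": -1},  "lb": -10,   "ub": 0},
    {"id": "EX_o2",   "stoich": {"o2_e": -1},   "lb": -30,   "ub": 0},
    {"id": "EX_co2",  "stoich": {"co2_e": -1},  "lb": 0,     "ub": 1000},
    {"id": "EX_etoh", "stoich": {"etoh_e": -1}, "lb": 0,     "ub": 1000},
    {"id": "GLCt",    "stoich": {"glc_e": -1, "glc": 1}, "lb": 0, "ub": 1000},
    {"id": "GLYC",    "stoich": {"glc": -1, "adp": -2, "nad": -2, "pyr": 2, "atp": 2, "nadh": 2}, "lb": 0, "ub": 1000},
    {"id": "FERM",    "stoich": {"pyr": -1, "nadh": -1, "etoh_e": 1, "co2_e": 1, "nad": 1}, "lb": 0, "ub": 1000},
    {"id": "TCA",     "stoich": {"pyr": -1, "nad": -4, "adp": -1, "co2_e": 3, "nadh": 4, "atp": 1}, "lb": 0, "ub": 1000},
    {"id": "ETC",     "stoich": {"nadh": -1, "o2_e": -0.5, "adp": -2, "nad": 1, "atp": 2}, "lb": 0, "ub": 1000},
    {"id": "ATPM",    "stoich": {"atp": -1, "adp": 1}, "lb": 0.05, "ub": 1000},
    {"id": "PROT_SYN", "stoich": {"pyr": -2, "atp": -4, "protein": 1, "adp": 4}, "lb": 0, "ub": 1000},
    {"id": "LIP_SYN",  "stoich": {"pyr": -4, "atp": -8, "nadh": -6, "lipid": 1, "adp": 8, "nad": 6}, "lb": 0, "ub": 1000},
    {"id": "POLY_SYN", "stoich": {"glc": -1, "atp": -1, "polysacch": 1, "adp": 1}, "lb": 0, "ub": 1000},
    {"id": "RNA_SYN",  "stoich": {"glc": -1.5, "atp": -6, "RNA": 1, "adp": 6}, "lb": 0, "ub": 1000},
    {"id": "DNA_SYN",  "stoich": {"glc": -1.5, "atp": -7, "nadh": -1, "DNA": 1, "adp": 7, "nad": 1}, "lb": 0, "ub": 1000},
    {"id": "STO_SYN",  "stoich": {"glc": -1, "atp": -1, "storage": 1, "adp": 1}, "lb": 0, "ub": 1000},
    {"id": "EX_biomass", "stoich": {"biomass": -1}, "lb": 0, "ub": 1000}
  ]
}
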