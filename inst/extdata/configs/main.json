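{
  "scenario": "main",
  "stride": 100,
  "model": {
    "et": {
      "F0": 200000,
      "F1": 200000000,
      "tau": 150000000
    },
    "alpha": 0.00022,
    "beta": 2.7e-05,
    "aeolian_p_rate": 27,
    "aeolian_mode": "rate",
    "atm_cap": 28000000,
    "ocean_sat_conc": 2.2e-06,
    "rainout_land_frac": 0.695652173913044,
    "riverine_ms_frac": 0.9,
    "epsilon": 0.3,
    "tau_sub": 100000000,
    "mixing": {
      "F0": 1e-08,
      "F1": 3e-08,
      "tau": 1500000000
    },
    "volcanism": {
      "V_arc": 2.75,
      "V_mor": 20,
      "V_hotspot": 2.25,
      "E_arc": 5,
      "E_mor": 4.6,
      "E_hotspot": 4.6,
      "f": 3,
      "tau": 500000000
    },
    "hydrothermal": {
      "H0": 1000000000,
      "tau": 1500000000
    },
    "seaspray_rate": 4.84280262673614e+15,
    "growth": {
      "model": "piecewise_linear",
      "A0_frac": 0.01,
      "t_knee": 1500000000,
      "frac_knee": 0.666666666666667
    },
    "cc_rock_growth": false,
    "core_fraction": 0.9,
    "dt": 5000,
    "n_steps": 900000,
    "p_molar_mass": 0.0309738
  },
  "structure": {
    "rock_masses": {
      "ATM": 5.1e+18,
      "OCEAN": 1.4e+21,
      "CC": 1.6e+22,
      "OC": 9e+21,
      "MS": 2.6e+20,
      "UM": 1.1e+24,
      "LM": 3e+24,
      "CORE": 2e+24
    },
    "modern_p": {
      "ATM": 28000000,
      "OCEAN": 93000000000000,
      "CC": 1.4e+19,
      "OC": 7.2e+18,
      "MS": 4e+18,
      "UM": 2.2e+20,
      "LM": 6e+20,
      "CORE": 5.8e+21
    },
    "ocean_volume": 1.4e+21,
    "area_earth": 510000000,
    "area_ocean": 360000000,
    "area_land_modern": 148000000,
    "rho_cc": 2700,
    "rho_mantle": 3300
  },
  "seeding": {
    "bse_total": 8.4e+20,
    "caps": {
      "ATM": 28000000,
      "OCEAN": 93000000000000,
      "CC": 100,
      "MS": 100
    },
    "rng_seed": 1
  }
}
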