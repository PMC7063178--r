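{
  "simulation": {
    "t_span": [0, 70000],
    "n_points": 1401,
    "rel_tol": 1e-05,
    "abs_tol": 1e-07
  },
  "tail_fraction": 0.1,
  "open_loop": {
    "NCD": {
      "u1": {
        "mode": "zero"
      },
      "u2": {
        "mode": "steady_state_amplified",
        "schedule": "frozen",
        "amplify": 1
      }
    },
    "DIO": {
      "u1": {
        "mode": "steady_state_amplified",
        "schedule": "continuous",
        "amplify": 1.3
      },
      "u2": {
        "mode": "steady_state_amplified",
        "schedule": "frozen",
        "amplify": 1
      }
    }
  },
  "controllers": {
    "upr": {
      "kp": 0,
      "ki": 0.0691,
      "kd": 0,
      "output_limits": [0, 500]
    },
    "insulin": {
      "kp": 0.2134,
      "ki": 0.10329,
      "kd": -0.1082,
      "output_limits": [0, 2000]
    }
  },
  "loop1": {
    "readout": "pPERK_ratio",
    "input": "u1",
    "controller": "upr",
    "initial_output": 92.1854543161758,
    "references": {
      "low": 0.5,
      "high": 0.8
    }
  },
  "cases": {
    "I": {
      "readout": "IRpY",
      "input": "u2",
      "controller": "insulin",
      "initial_output": 47.810941875555,
      "references": {
        "low": 0.229845310989524,
        "high": 0.408630976995746
      }
    },
    "II": {
      "readout": "IRSpY",
      "input": "u2",
      "controller": "insulin",
      "initial_output": 47.810941875555,
      "references": {
        "low": 0.391720057945904,
        "high": 1.0060205875601
      }
    },
    "III": {
      "readout": "insulin_sensitivity",
      "input": "u2",
      "controller": "insulin",
      "initial_output": 47.810941875555,
      "references": {
        "low": 1.7,
        "high": 4.7
      }
    }
  },
  "verdict_thresholds": {
    "flux_unfolded": 0.0921854239082158,
    "insulin_sensitivity": 3.98366510965427,
    "pPERK_ratio": 0.661957529805226,
    "pIRE1a_ratio": 0.661957529805226,
    "peIF2a_ratio": 0.657928776358573
  },
  "expected_verdicts": {
    "I": {
      "high_low": {
        "er_stress": "high",
        "insulin_sensitivity": "low",
        "upr": "high"
      },
      "high_high": {
        "er_stress": "high",
        "insulin_sensitivity": "low",
        "upr": "high"
      },
      "low_high": {
        "er_stress": "low",
        "insulin_sensitivity": "high",
        "upr": "low"
      },
      "low_low": {
        "er_stress": "low",
        "insulin_sensitivity": "low",
        "upr": "low"
      }
    },
    "II": {
      "high_low": {
        "er_stress": "high",
        "insulin_sensitivity": "low",
        "upr": "high"
      },
      "high_high": {
        "er_stress": "high",
        "insulin_sensitivity": "low",
        "upr": "high"
      },
      "low_high": {
        "er_stress": "low",
        "insulin_sensitivity": "high",
        "upr": "low"
      },
      "low_low": {
        "er_stress": "low",
        "insulin_sensitivity": "low",
        "upr": "low"
      }
    },
    "III": {
      "high_low": {
        "er_stress": "high",
        "insulin_sensitivity": "low",
        "upr": "high"
      },
      "high_high": {
        "er_stress": "high",
        "insulin_sensitivity": "high",
        "upr": "high"
      },
      "low_high": {
        "er_stress": "low",
        "insulin_sensitivity": "high",
        "upr": "low"
      },
      "low_low": {
        "er_stress": "low",
        "insulin_sensitivity": "low",
        "upr": "low"
      }
    }
  },
  "anchors": [
    {
      "id": "sens_low_pPERK_low_pAKT",
      "scenario": "case_III_low_low",
      "type": "steady",
      "readout": "insulin_sensitivity",
      "target": 1.7,
      "rel_tol": 0.15
    },
    {
      "id": "sens_low_pPERK_high_pAKT",
      "scenario": "case_III_low_high",
      "type": "steady",
      "readout": "insulin_sensitivity",
      "target": 4.7,
      "rel_tol": 0.15
    },
    {
      "id": "upr_plateau_high",
      "scenario": "case_I_high_low",
      "type": "steady_mean",
      "readouts": [
        "pPERK_ratio",
        "pIRE1a_ratio",
        "peIF2a_ratio"
      ],
      "target": 0.8,
      "rel_tol": 0.15
    },
    {
      "id": "upr_plateau_low",
      "scenario": "case_I_low_high",
      "type": "steady_mean",
      "readouts": [
        "pPERK_ratio",
        "pIRE1a_ratio",
        "peIF2a_ratio"
      ],
      "target": 0.5,
      "rel_tol": 0.15
    },
    {
      "id": "flux_zero_time",
      "scenario": "case_I_low_low",
      "type": "flux_zero_time",
      "readout": "flux_unfolded",
      "target": 6000,
      "rel_tol": 0.15,
      "threshold": 0.01
    }
  ]
}
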