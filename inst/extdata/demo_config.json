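{
  "seed": 1,
  "proteome": {"n_proteins": 40, "length_min": 80, "length_max": 300},
  "selection": {"length_min": 6, "length_max": 16,
                "gravy_low": -2, "gravy_high": 2,
                "max_peptides_per_protein": 1},
  "screening": {"snr_threshold": 3, "snr_high": 10, "rt_tolerance_min": 0.2,
                "ratio_threshold": 0.95, "noise_sd": 10,
                "snr_levels": [0.5, 2, 5, 20, 100]},
  "cohort": {"n_cases_discovery": 50, "n_controls_discovery": 50,
             "n_cases_validation": 96, "n_controls_validation": 95,
             "n_differential": 8, "planted_fc": 1.5,
             "cv_biological": 0.2, "cv_technical": 0.2, "n_tech_reps": 2},
  "discovery": {"fc_threshold": 1.2, "alpha": 0.05},
  "qc": {"accuracy_tolerance_pct": 20, "cv_threshold_pct": 20,
         "stability_tolerance_pct": 20, "calibration_error_cv": 0.05,
         "precision_cv": 0.05, "n_fail_qc": 2},
  "evaluation": {"train_fraction": 0.7, "random_states": [1, 2, 3, 4, 5],
                 "lambda": 0.01}
}
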