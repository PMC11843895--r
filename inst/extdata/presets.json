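{
  "control": {
    "comment": "Unmethylated amplicon. false_mod_rate is the calibration constant chosen so the confidence-thresholded (0.65) global 5mC level of simulated control reads is about 0.04; see the methods vignette for the derivation.",
    "truth": {
      "c_pqs": 0.0,
      "g_pqs": 0.0,
      "c_nonpqs": 0.0,
      "g_nonpqs": 0.0,
      "site_sd_pqs": 0.0,
      "site_sd_nonpqs": 0.0
    },
    "noise": {
      "high_conf_concentration": 24,
      "low_conf_concentration": 3,
      "p_low_conf_inside_pqs": 0.5,
      "p_low_conf_outside": 0.02,
      "false_mod_rate": 0.031
    }
  },
  "dnmt3a": {
    "comment": "De novo methyltransferase treatment: strand- and region-specific truth. c_* = coding (C-rich, +) strand, g_* = template (G-rich, -) strand. site_sd_* are between-site truth standard deviations on the probability scale, chosen so that the mean +/- SEM convention over the observed site counts matches the reported +/-3 percentage-point SEMs (0.03*sqrt(26) ~ 0.15 inside the PQS region, 0.03*sqrt(69) ~ 0.25 outside).",
    "truth": {
      "c_pqs": 0.58,
      "g_pqs": 0.33,
      "c_nonpqs": 0.49,
      "g_nonpqs": 0.47,
      "site_sd_pqs": 0.15,
      "site_sd_nonpqs": 0.25
    },
    "noise": {
      "high_conf_concentration": 24,
      "low_conf_concentration": 3,
      "p_low_conf_inside_pqs": 0.5,
      "p_low_conf_outside": 0.02,
      "false_mod_rate": 0.01
    }
  },
  "msssi": {
    "comment": "CpG-specific prokaryotic methyltransferase treatment: near-uniform methylation on both strands.",
    "truth": {
      "c_pqs": 0.62,
      "g_pqs": 0.62,
      "c_nonpqs": 0.62,
      "g_nonpqs": 0.62,
      "site_sd_pqs": 0.15,
      "site_sd_nonpqs": 0.15
    },
    "noise": {
      "high_conf_concentration": 24,
      "low_conf_concentration": 3,
      "p_low_conf_inside_pqs": 0.5,
      "p_low_conf_outside": 0.02,
      "false_mod_rate": 0.01
    }
  }
}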