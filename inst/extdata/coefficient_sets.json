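{
  "published_ukall": {
    "name": "PI_UKALL (published)",
    "provenance": "published_ukall",
    "comment": "UKALL relapse prognostic index. CYTO_GR/CYTO_HR are mapped onto the cohort schema's frg/urg flags; edit the covariate names here to use alternative genetic definitions.",
    "terms": {
      "covariate": ["tau_d29", "frg", "urg", "wbc_log"],
      "coefficient": [-0.218, -0.440, 1.066, 0.138]
    }
  },
  "derived_ukall": {
    "name": "PI_UKALL (derived on COG data)",
    "provenance": "derived_ukall",
    "terms": {
      "covariate": ["tau_d29", "frg", "urg", "wbc_log"],
      "coefficient": [-0.136, -0.913, 0.692, 0.166]
    }
  },
  "published_cog": {
    "name": "PI_COG",
    "provenance": "published_cog",
    "terms": {
      "covariate": ["tau_d29", "tau_d8", "frg", "urg", "wbc_log", "cns2", "cns3", "age"],
      "coefficient": [-0.102, -0.040, -0.741, 0.644, 0.156, 0.386, 0.364, 0.061]
    },
    "cutpoints": [-1.377, -0.589, 0.093],
    "labels": ["Low", "Standard", "Intermediate", "High"]
  }
}
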