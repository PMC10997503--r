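{
  "name": "Approximate COG clinical risk classification (synthetic stand-in)",
  "comment": "First-match-wins rules built only from publicly described factors (NCI risk, FRG/URG, D8/D29 MRD thresholds, CNS status). The exact trial algorithm tables are not public; these rules are an approximation for demonstration and testing. MRD values are fractions (0.01% = 1e-4).",
  "default": "HR",
  "rules": [
    {
      "label": "VHR",
      "when": [
        {"field": "urg", "op": "eq", "value": true},
        {"field": "d29_mrd", "op": "ge", "value": 1e-4}
      ]
    },
    {
      "label": "SR-Fav",
      "when": [
        {"field": "nci_risk", "op": "eq", "value": "SR"},
        {"field": "frg", "op": "eq", "value": true},
        {"field": "d8_mrd", "op": "lt", "value": 0.01},
        {"field": "d29_mrd", "op": "lt", "value": 1e-4},
        {"field": "cns", "op": "eq", "value": "CNS1"}
      ]
    },
    {
      "label": "SR-High",
      "when": [
        {"field": "nci_risk", "op": "eq", "value": "SR"},
        {"field": "d29_mrd", "op": "ge", "value": 1e-4}
      ]
    },
    {
      "label": "SR-Avg",
      "when": [
        {"field": "nci_risk", "op": "eq", "value": "SR"}
      ]
    },
    {
      "label": "HR-Fav",
      "when": [
        {"field": "nci_risk", "op": "eq", "value": "HR"},
        {"field": "frg", "op": "eq", "value": true},
        {"field": "d29_mrd", "op": "lt", "value": 1e-4}
      ]
    }
  ]
}
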