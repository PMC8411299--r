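{
  "description": "Synthetic comorbidity grouper for testing and simulation: a replaceable stand-in with the same shape as an Elixhauser-style weighted index (diagnosis code -> category, category -> integer weight). Weights are invented; supply a licensed grouper for real analyses.",
  "weights": {
    "chf": 7,
    "arrhythmia": 5,
    "pulmonary": 3,
    "diabetes_cx": 2,
    "renal_failure": 5,
    "liver_disease": 11,
    "metastatic_cancer": 12,
    "coagulopathy": 3,
    "obesity": -4,
    "depression": -3
  },
  "categories": {
    "I5022": "chf", "I5032": "chf", "I110": "chf",
    "I4891": "arrhythmia", "I479": "arrhythmia", "I4901": "arrhythmia",
    "J449": "pulmonary", "J4520": "pulmonary", "J479": "pulmonary",
    "E1122": "diabetes_cx", "E1142": "diabetes_cx", "E1065": "diabetes_cx",
    "N186": "renal_failure", "N184": "renal_failure", "N189": "renal_failure",
    "K7469": "liver_disease", "K7030": "liver_disease", "K766": "liver_disease",
    "C7800": "metastatic_cancer", "C787": "metastatic_cancer", "C795": "metastatic_cancer",
    "D689": "coagulopathy", "D65": "coagulopathy", "D6959": "coagulopathy",
    "E6601": "obesity", "E669": "obesity", "Z6841": "obesity",
    "F329": "depression", "F331": "depression", "F341": "depression"
  }
}
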