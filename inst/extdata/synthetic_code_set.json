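{
  "description": "Synthetic stand-in code set for testing and simulation. Codes are ICD-10-CM-like strings invented for this package; they are NOT the licensed AAST / HCUP Surgery Flags lists, which must be supplied by the user for real analyses.",
  "egs_dx": {
    "appendicitis": ["K3580", "K3520", "K3521", "K3530"],
    "cholecystitis": ["K8100", "K8110", "K8000", "K8001"],
    "bowel_obstruction": ["K5660", "K5641", "K5650", "K5600"],
    "perforated_viscus": ["K631", "K2511", "K2651", "K2711"],
    "hernia_complicated": ["K4000", "K4100", "K4230", "K4330"],
    "soft_tissue_infection": ["L0311", "L0231", "M7260", "L08891"]
  },
  "complication_dx": [
    "I2101", "J9601", "I2699", "J189",
    "K9161", "T814XXA", "N170", "R570"
  ],
  "operation_proc": [
    "0DTJ4ZZ", "0FT44ZZ", "0DNE0ZZ", "0DB60ZZ",
    "0WQF0ZZ", "0JQC0ZZ", "0D9J3ZZ", "0W9G3ZZ",
    "0DTN0ZZ", "0FC94ZZ"
  ]
}
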