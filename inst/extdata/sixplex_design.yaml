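# Channel design for the serum-stability experiment: five disease pools
# plus the pooled-QC bridging sample on channel 126.
channels:
  - {label: "126", role: bridging, condition: QC}
  - {label: "127", role: sample, condition: Alzheimer}
  - {label: "128", role: sample, condition: Parkinson}
  - {label: "129", role: sample, condition: Depression}
  - {label: "130", role: sample, condition: Schizophrenia}
  - {label: "131", role: sample, condition: Stroke}
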