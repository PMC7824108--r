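# Sixplex LPA/PA panel as printed in the acquisition method.  The PA list
# contains a duplicate 36:2 entry on purpose; the builder deduplicates it
# with a warning.
panel:
  - LPA(16:0)
  - LPA(18:0)
  - LPA(18:1)
  - LPA(18:2)
  - LPA(20:4)
  - PA(32:0)
  - PA(34:1)
  - PA(34:2)
  - PA(36:0)
  - PA(36:2)
  - PA(36:3)
  - PA(36:2)
  - PA(36:4)
  - PA(38:4)
rule_mode: paper_nominal
acquisition:
  collision_energy: 46
  polarity: positive
channels:
  - {label: "126", role: bridging}
  - {label: "127", role: sample}
  - {label: "128", role: sample}
  - {label: "129", role: sample}
  - {label: "130", role: sample}
  - {label: "131", role: sample}
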