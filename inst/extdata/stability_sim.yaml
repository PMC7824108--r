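# Synthetic serum-stability design: 6 channels (5 disease pools + QC
# bridge), incubation at 0 h and 20 h, 3 replicate runs per time point.
design: sixplex
species:
  - FA(20:4)
  - FA(18:1)
  - LPA(18:2)
  - 12-HETE
  - TXB2
times: [0, 20]
replicates: 3
set_effect_sigma: 0.5
channel_bias_sigma: 0.1
noise_sigma: 0.1
true_fold:
  - {species: "FA(20:4)", condition: Alzheimer, time_h: 20, fold: 2.0}
  - {species: "LPA(18:2)", condition: Stroke, time_h: 20, fold: 1.5}
  - {species: "TXB2", condition: Schizophrenia, time_h: 20, fold: 0.5}
seed: 20
channels:
  - {label: "126", role: bridging, condition: QC}
  - {label: "127", role: sample, condition: Alzheimer}
  - {label: "128", role: sample, condition: Parkinson}
  - {label: "129", role: sample, condition: Depression}
  - {label: "130", role: sample, condition: Schizophrenia}
  - {label: "131", role: sample, condition: Stroke}
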