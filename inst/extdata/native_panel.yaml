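# Native (underivatized) SRM panel: the lyso-phospholipids, DAG, LPA and
# PA monitored without TMT labeling.
panel:
  - LPC(16:0)
  - LPE(18:1)
  - DAG(18:1/18:1)
  - LPA(16:0)
  - LPA(18:1)
  - PA(36:2)
mode: native
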