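name,formula,n_carboxy,n_phospho_monoester,synonyms
PGD2,C20H32O5,1,0,prostaglandin D2
PGF2a,C20H34O5,1,0,prostaglandin F2alpha
LTB4,C20H32O4,1,0,leukotriene B4
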