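name,n_chains,tail_formula_per_pair,head_formula,n_exchangeable_H
DMPE,2,C26H54,C7H12NO8P,3
DMPG,2,C26H54,C8H12O10PNa,2
TMCL,4,C26H54,C9H8O17P2Na2,1
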