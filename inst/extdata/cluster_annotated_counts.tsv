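cluster	n_annotated
transient	74
long_term_changing	79
long_term_constant	50
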