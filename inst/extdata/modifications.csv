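# source: phospho-site acid dissociation constants used for S/T (and by extension Y) phosphorylation
modification,pka,polarity
phospho,1.2,acid
phospho,6.5,acid
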