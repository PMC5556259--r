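corpus,n_items,n_validated,n_invalidated
forum,53,39,14
facebook,53,36,17
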