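>SYNH synthetic two-chain disulfide fixture, heavy-like chain (not a real antibody)
MKTGSCLDEPWQRCSTKDGAEVLNCGKCSPTSGKWFDQYV
>SYNL synthetic two-chain disulfide fixture, light-like chain (not a real antibody)
GVSWCKDERANQCTLGKRIPFYVDSTGKWE
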