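>sp|SYNTOY1|1 synthetic toy protein, Pro/Ala rich
MKAPLLGPRASTPGKAPEWAQPLDAKRPGSA
>sp|SYNTOY2|201-230 synthetic fragment with range annotation
AGPKKDLSTAPYRAPQGMWPAETSIKPLVA
>sp|SYNTOY3|1 synthetic histone-like K/R rich protein
MSGRGKQGGKARAKAKTRSSRAGLQFPVGRV
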