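 3 6
s1        MKC-CG
s2        MK-ACG
s3        M-CAC-
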