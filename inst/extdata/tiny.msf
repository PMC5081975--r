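!!AA_MULTIPLE_ALIGNMENT 1.0

 demo.msf  MSF: 6  Type: P  Check: 0 ..

 Name: s1 Len: 6  Check: 0  Weight: 1.00
 Name: s2 Len: 6  Check: 0  Weight: 1.00
 Name: s3 Len: 6  Check: 0  Weight: 1.00

//

s1  MKC.CG
s2  MK.ACG
s3  M.CAC.
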