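>seq01
GGKCD--D-DVCYERQR--CK---E-RC-FGMMN-K
>seq02
Q--CES-LEE-C---SF--CKPIWM--CID-LKC-Q
>seq03
RANC-QGG---C-GH-D--CYCD--LWCHF--FDFS
>seq04
W-GC-Q-FP-DC----R-HC--A-K--C-GKVKE-V
>seq05
NP-CN-WV-C-C-TY-CNCC----P--CESMIKQY-
>seq06
A-DCE-GQ--SC-LHKVIKCSEA--LLCFQ-IRK--
>seq07
-TCC--YI-CHC--EHYL-CY-HS-ICCCH-YFDLH
>seq08
F--CKDYL-MTC-CP--FKCF--VCLSCG---N-VN
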