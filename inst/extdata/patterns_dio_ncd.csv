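"id","readout","condition_a","condition_b","relation","provenance"
"atf6a_up","ATF6a","DIO","NCD","greater","liver qPCR: ATF6a mRNA elevated in DIO (n = 6)"
"pire1a_ratio_up","pIRE1a_ratio","DIO","NCD","greater","immunoblot: phospho-IRE1a over total IRE1a elevated in DIO liver (n = 4)"
"pperk_ratio_up","pPERK_ratio","DIO","NCD","greater","immunoblot: phospho-PERK (Thr980) over total PERK elevated in DIO liver (n = 4)"
"peif2a_ratio_up","peIF2a_ratio","DIO","NCD","greater","immunoblot: phospho-eIF2a (Ser51) over total eIF2a elevated in DIO liver (n = 4)"
"pjnk_up","pJNK","DIO","NCD","greater","immunoblot: JNK phosphorylation elevated in DIO liver"
"pikkb_up","pIKKb","DIO","NCD","greater","immunoblot: IKKb phosphorylation elevated in DIO liver"
"pnfkb_up","pNFkB","DIO","NCD","greater","immunoblot: NF-kB phosphorylation elevated in DIO liver"
"sens_down","insulin_sensitivity","DIO","NCD","less","pAkt/Akt signal ratio (insulin sensitivity) reduced under stress"
"irpy_down","IRpY","DIO","NCD","less","immunoblot: insulin receptor phospho-tyrosine reduced in DIO liver"
"irspy_down","IRSpY","DIO","NCD","less","immunoblot: IRS-1 phospho-tyrosine reduced in DIO liver"
"pip3_down","PIP3","DIO","NCD","less","PIP3 level reduced under stress"
"pfoxo1_down","pFoxO1","DIO","NCD","less","FoxO1 phosphorylation reduced in DIO liver"
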