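acid,salt,k_M1ks1,k_ci95,note
none,KCl,3.2,1,no acid; rate referenced to salt concentration
H2SO4,KCl,53,9,
triflic,KCl,64,5,78% HMF yield at ~90% conversion
HCl,KCl,78,8,81% HMF yield at ~90% conversion
H2SO4,NaCl,55,20,
triflic,NaCl,53,6,
triflic,LiCl,69,10,
triflic,CaCl2,71,10,salt at 2.5 mM
HBr,none,28,3,
triflic,KBr,22,3,
triflic,NaBr,25,2,
triflic,LiBr,29,1,
HI,none,2.7,1,
triflic,KI,4.0,1,
triflic,KF,1.9,1,
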