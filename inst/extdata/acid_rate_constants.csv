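solvent,acid,k_M1ks1,k_ci95,hmf_yield_pct,yield_ci95
water,H2SO4,0.14,0.01,38,1
water,triflic,0.15,0.03,35,2
water,HCl,0.14,0.01,40,1
90% GVL,H2SO4,20,1,57,1
90% GVL,triflic,21,4,56,2
90% GVL,HCl,62,4,78,1
90% THF,H2SO4,5.8,1,70,1
90% THF,triflic,5.6,1,72,5
90% THF,HCl,28,5,76,1
90% dioxane,H2SO4,10,2,64,1
90% dioxane,triflic,7.7,1,57,2
90% dioxane,HCl,95,6,73,1
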