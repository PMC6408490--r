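system,catalyst_anion,dG_formation_kJmol,dG_abstraction_kJmol,dG_total_kJmol,note
water,H+,57,35,92,
water,H+/Cl-,58,35,93,
75% GVL,H+,49,35,84,
75% GVL,H+/Cl-,44,30,74,
90% GVL,H+,43,33,76,
90% GVL,H+/Cl-,38,29,67,formation value carries a dissociation correction derived from the 75% GVL system
90% GVL,H+/TfO-,43,33,76,anion migrated from the active site during sampling; components taken from the anion-free 90% GVL system
90% GVL,H+/HSO4-,45,33,78,
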