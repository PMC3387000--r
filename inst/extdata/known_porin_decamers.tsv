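protein	group	decamer
PhoE_Se	reference_porin	IVAIGLTYQF
PhoE_Ec	reference_porin	IVAVGMTYQF
OmpF_Ec	reference_porin	TVAVGIVYQF
OmpC_Ec	reference_porin	IVALGLVYQF
TM0476	ompB_homolog	YLYLKASVAF
TRQ2_0459	ompB_homolog	FGFITYRLAF
Tpet_0444	ompB_homolog	YLYLKASVAF
Tnap_0258	ompB_homolog	YLYLKASVAF
CTN_0196	ompB_homolog	YLYLKAEVEF
Tmel_0175	ompB_homolog	YAKLSWSVSF
Fnod_1725	ompB_homolog	NLKLTYSASF
Kole_1501	ompB_homolog	YAYVGYYAAF
Theba_0319	ompB_homolog	SLGLYFDKYF
Pmob_0056	ompB_homolog	YLYLKAEFKF
Tlet_1718	putative_analog	TLAWRMRVYF
THA_406	putative_analog	TLNMNAHFDF
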