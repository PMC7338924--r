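taxonomy,category,keyword,ambiguous_flag,context_list
ecig,ecig,e-cig,0,
ecig,ecig,e-cigs,0,
ecig,ecig,ecig,0,
ecig,ecig,ecigs,0,
ecig,ecig,electroniccigarette,0,
ecig,ecig,ecigarette,0,
ecig,ecig,ecigarettes,0,
ecig,ecig,vape,0,
ecig,ecig,vapers,0,
ecig,ecig,vaping,0,
ecig,ecig,vapes,0,
ecig,ecig,e-liquid,0,
ecig,ecig,ejuice,0,
ecig,ecig,eliquid,0,
ecig,ecig,e-juice,0,
ecig,ecig,vapercon,0,
ecig,ecig,vapeon,0,
ecig,ecig,vapefam,0,
ecig,ecig,vapenation,0,
ecig,ecig,juul,0,
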