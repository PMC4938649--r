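gene	allele	balancer	chrom	start	end	type
knirps	kni-ri-1	TM3	3L	20707101	20707352	deletion
pink	p-p	TM3	3R	6661619	6661619	deletion
Tubby	Tb-1	TM6B	3R	26656728	26656742	deletion
Tubby	Tb-1	TM6B	3R	26657089	26657157	deletion
ebony	e-1	TM3,TM6,TM6B	3R	21231832	21231838	TE_insertion
Stubble	Sb-1	TM3	3R	16141939	16141942	TE_insertion
Serrate	Ser-1	TM3	3R	27172910	27172913	TE_insertion
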