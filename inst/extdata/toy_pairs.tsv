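sm_id	smiles	mirna_id	direction
fluorouracil	C1=C(C(=O)NC(=O)N1)F	hsa-miR-3074-5p	down
fluorouracil	C1=C(C(=O)NC(=O)N1)F	hsa-miR-3170	down
aspirin	CC(=O)OC1=CC=CC=C1C(=O)O	hsa-miR-3131	up
caffeine	CN1C=NC2=C1C(=O)N(C(=O)N2C)C	hsa-miR-3614-3p	up
ibuprofen	CC(C)CC1=CC=C(C=C1)C(C)C(=O)O	hsa-miR-3616-3p	down
phenol	Oc1ccccc1	hsa-miR-449b-5p	up
nicotinamide	C1=CC(=CN=C1)C(=O)N	hsa-miR-616-3p	down
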