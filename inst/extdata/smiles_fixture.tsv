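id	smiles
fluorouracil	C1=C(C(=O)NC(=O)N1)F
aspirin	CC(=O)OC1=CC=CC=C1C(=O)O
caffeine	CN1C=NC2=C1C(=O)N(C(=O)N2C)C
ibuprofen	CC(C)CC1=CC=C(C=C1)C(C)C(=O)O
ethanol	CCO
phenol	Oc1ccccc1
acetone	CC(=O)C
nicotinamide	C1=CC(=CN=C1)C(=O)N
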