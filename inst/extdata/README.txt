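Small plain-text fixtures for tests and examples.

smiles_fixture.tsv    real, well-known drug/solvent SMILES (id, smiles)
mirnas_fixture.fasta  real human mature miRNA sequences (miRBase-style ids)
toy_pairs.tsv         SYNTHETIC illustrative pairings of the two files
                      above; the molecule-miRNA links are invented for
                      format/plumbing tests and carry no biological claim
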