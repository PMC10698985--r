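dataset	sequences	interaction_sites	noninteraction_sites
Dset_186	186	5517	30702
Dset_72	72	1923	16217
PDBset_164	164	6096	27585
Dset_186_72_PDB164	422	13536	74504
Dset_448	448	15810	100690
large	9982	427687	3826511
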