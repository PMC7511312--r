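gene,accession,forward,reverse
psy,AF305430,AGGGGATGCGGATGGATTTGC,AGTCATCAGGCCAACAGTGCC
crtR-b,AF162276,TGCTGCTACCACGATGCTGT,CATGCAGGCAGACTTTGGGC
bkt 1,GU143688,CACAGCTAGACGGATGCAGCT,GCCTGCAACCTCCTTCTCCTT
actin,DV203941,GCGGGACATCAAGGAGAAGCT,TCGTAGTGCTTCTCCAGTGCC
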