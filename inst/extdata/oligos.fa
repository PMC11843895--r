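>MGMT-G4 G4-forming oligonucleotide from the MGMTp PQS
GGGCCGGGGCGCGCGGGGGCGGAG
>MGMT-G4-mut G4-disrupted analog of MGMT-G4
GTGCCGGAGCGCGCGGAGGCGGAG
>MGMT-C C-rich complement of MGMT-G4
CTCCGCCCCCGCGCGCCCCGGCCC
>non-specific-control control oligonucleotide without CpG sites
CTGAATACTACTTCCTACCCCTTACCTGAT
>MGMT-ds1-top top strand of the MGMT-ds1 duplex (single central CpG)
GGTCCTGCAGGCGCCCTCACTT
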