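target	direction	sequence
Beta Actin	Forward	AATGTGGCCGAGGACTTTGAT
Beta Actin	Reverse	AGTGGGTGGCTTTTAGGAT
NRXN1a	Forward	AACGCAAATCACCGCCGGA
NRXN1a	Reverse	GCCTTCTTTGGCATGTACAAG
NRXN1b	Forward	GCCTATTGCAATCTACAGGTC
NRXN1b	Reverse	AACCTATGGCCAGTCTGTCT
NRXN1g	Forward	GCCAGACAGACATGGATATGAG
NRXN1g	Reverse	TGAGGCCACAAGGATGTCAT
NRXN1+SS4	Forward	AATGGCTACTCGACAAAGGG
NRXN1+SS4	Reverse	GCGATGTTGGCATCGTTTTC
NRXN1-SS4	Forward	TACCCTGCAGGGCGTCAGCT
NRXN1-SS4	Reverse	CGGCTGCCATATTCAGAACT
NRXN2a	Forward	ACTGAAGAGTCCTGTGCCAA
NRXN2a	Reverse	CCTTCCCAAAGATGTATGTGG
NRXN2b	Forward	AGCAACACTTCGCTGCCTC
NRXN2b	Reverse	GAAGGGAAGCAAATCCGGGTG
NRXN2+SS4	Forward	CTTTGATAACGAGCGCCTGG
NRXN2+SS4	Reverse	GCCTGGCTGTTGAAGATGGT
NRXN2-SS4	Forward	TACCCGGCAGGCCGCCA
NRXN2-SS4	Reverse	CACCTTGAGCCCATTGTAGT
NRXN3a	Forward	ACCCAGTACCACCTGCCAGGAA
NRXN3a	Reverse	TCATTGCACTGGTTTCCAGAA
NRXN3b	Forward	GCATCACTCAGTGCCTATTTC
NRXN3b	Reverse	CAAGATGCCATCCTTCACAG
NRXN3+SS4	Forward	GCAACACTGATAATGAACGC
NRXN3+SS4	Reverse	TGCGCCTGAGTGTTGAAGAT
NRXN3-SS4	Forward	ATTATCCTACAGGCCGGCAG
NRXN3-SS4	Reverse	TTCTCAGCCGCCATGTTCAG
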