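element	five_prime_nick	tsd	three_prime_nick
1-1	tacaaaagt	aaatgactagtagga	taataaaca
1-2	acttgacat	agctatgaaaatcgt	tggaccatc
3-2	tttatgaag	aatcttcgtt	cagtcctgc
4-2	acaacattt	aaagatatctcgtttg	tggagaacg
5-1	ctgcaatat	agtactactact	aatgttatc
5-1d1	ttaagaaag	aaatgtgtctcaacg	cgaccaacg
6-1	gaagagacc	aaaacctagtctggag	tacaaagta
6-1d2	ttataaaag	aaaactaatcttaa	gaaaaatac
7-1	atggaagat	aaagaatctggcttt	ttgtaaaac
7-2	ctatggaag	aagaaggtaa	ccaactact
7L1	agggagttt	ttaagag	ttttattat
7L2	tcatataat	aattacctagca	cgaaatcta
8-1	gaacataac	aaaagatccaa	acgtatggt
9L3	caatcaacc	ccgtatt	gtagatttt
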