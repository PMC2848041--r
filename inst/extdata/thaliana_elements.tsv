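sadhu_number	locus_id	position
1-1	At2g10410	Chr2: 4014110-4013202
1-2	At1g30835	Chr1: 10967854-10966931
1-3	At5g28626	Chr5: 10632245-10632826; 10633568-10633948
1L1	At1g66795	Chr1: 24926769-24927016
2-1	At1g35112	Chr1: 12841125-12840206
2-1d1	At2g18535	Chr2: 8048795-8048610
3-1	At3g44042	Chr3: 15825096-15824141
3-2	At3g42658	Chr3: 14761424-14760388
3-1d1	At2g21905	Chr2: 9345876-9346247
3-1d2	At5g03205	Chr5: 762065-761915
3L1	At4g04925	Chr4: 2506188-2506806
4-1	At5g28913	Chr5: 10934749-10933814
4-2	At1g03420	Chr1: 846815-847698
4-2d1	At2g05027	Chr2: 1781076-1781386
5-1	At4g01525	Chr4: 660768-661723
5-1d1	At1g18195	Chr1: 6262595-6263382
5-1d2	At4g00953	Chr4: 410383-411018
5-2	At5g27927	Chr5: 9957820-9956864
6-1	At3g02515	Chr3: 525338-526263
6-1d1	At5g42095	Chr5: 16845951-16846349
6-1d2	At5g44565	Chr5: 17981087-17980529
6-1d3	At5g42237	Chr5: 16987448-16988447
6L1	At2g10935	Chr2: 4312891-4312205
7-1	At3g13438	Chr3: 4377991-4377083
7-2	At3g31442	Chr3: 12807354-12806392
7L1	At1g36745	Chr1: 13912120-13913031
7L2	At3g61625	Chr3: 22815058-22814684
7L3	At5g52140	Chr5: 21206508-21206698
8-1	At1g50735	Chr1: 18811080-18810175
8L1	At5g38915	Chr5: 15597647-15597844
8L2	At2g24745	Chr2: 10540693-10541337
8L3	At1g52615	Chr1: 19607182-19606826
9-1	At1g44935	Chr1: 16904928-16905344
9L1	At1g32455	Chr1: 11733481-11733785
9L2	At1g69365	Chr1: 26083199-26083479
10-1	At3g58865	Chr3: 21776975-21777729
10L1	At5g46395	Chr5: 18836667-18837050
10L2	At5g42945	Chr5: 17240081-17240294
10L3	At1g35255	Chr1: 12935906-12936263
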