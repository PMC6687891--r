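tag	variants	n_supporting_reads	disqualified	reason
AAAAAAAAAAAAAAA		5	FALSE	NA
CCCCCCCCCCCCCCC	4:C>T	4	FALSE	NA
GGGGGGGGGGGGGGG		3	FALSE	NA
ACACACACACACACA	7:C>-	6	FALSE	NA
GTGTGTGTGTGTGTA	2:G>A,10:G>T	3	FALSE	NA
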