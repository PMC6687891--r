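@dna_01
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_02
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_03
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_04
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@dna_05
ACACACACACACACA
+
IIIIIIIIIIIIIII
@dna_06
ACACACACACACACA
+
IIIIIIIIIIIIIII
@dna_07
ACACACACACACACA
+
IIIIIIIIIIIIIII
@dna_08
GTGTGTGTGTGTGTA
+
IIIIIIIIIIIIIII
@dna_09
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_10
AAAAAAAAAAAAAA
+
IIIIIIIIIIIIII
@dna_11
NAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_12
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_13
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_14
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@dna_15
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
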