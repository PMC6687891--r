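@dna_01
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_02
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_03
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_04
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
@dna_05
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@dna_06
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@dna_07
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@dna_08
TACACACACACACAC
+
IIIIIIIIIIIIIII
@dna_09
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@dna_10
TTTTTTTTTTTTTT
+
IIIIIIIIIIIIII
@dna_11
TTTTTTTTTTTTTTN
+
IIIIIIIIIIIIIII
@dna_12
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_13
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_14
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@dna_15
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
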