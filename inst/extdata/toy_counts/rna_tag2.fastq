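@rna_01
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_02
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_03
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_04
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
@rna_05
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
@rna_06
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@rna_07
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_08
TTTTTTTTTTTTTT
+
IIIIIIIIIIIIII
@rna_09
TTTTTTTTTTTTTTN
+
IIIIIIIIIIIIIII
@rna_10
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@rna_11
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@rna_12
TGTGTGTGTGTGTGT
+
IIIIIIIIIIIIIII
@rna_13
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_14
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_15
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
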