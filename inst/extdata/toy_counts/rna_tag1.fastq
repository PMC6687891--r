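@rna_01
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_02
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_03
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_04
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@rna_05
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@rna_06
GGGGGGGGGGGGGGG
+
IIIIIIIIIIIIIII
@rna_07
TTTTTTTTTTTTTTT
+
IIIIIIIIIIIIIII
@rna_08
AAAAAAAAAAAAAA
+
IIIIIIIIIIIIII
@rna_09
NAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_10
ACACACACACACACA
+
IIIIIIIIIIIIIII
@rna_11
ACACACACACACACA
+
IIIIIIIIIIIIIII
@rna_12
ACACACACACACACA
+
IIIIIIIIIIIIIII
@rna_13
AAAAAAAAAAAAAAA
+
IIIIIIIIIIIIIII
@rna_14
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
@rna_15
CCCCCCCCCCCCCCC
+
IIIIIIIIIIIIIII
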