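@rna_01
AAAAACCCCC
+
IIIIIIIIII
@rna_02
AAAAACCCCC
+
IIIIIIIIII
@rna_03
AAAAAGGGGG
+
IIIIIIIIII
@rna_04
AAAAACCCCC
+
IIIIIIIIII
@rna_05
NAAAAAAAAA
+
IIIIIIIIII
@rna_06
AAAAACCCCC
+
IIIIIIIIII
@rna_07
AAAAACCCCC
+
IIIIIIIIII
@rna_08
AAAAACCCCC
+
IIIIIIIIII
@rna_09
AAAAACCCCC
+
IIIIIIIIII
@rna_10
AAAAACCCCC
+
IIIIIIIIII
@rna_11
AAAAAGGGGG
+
IIIIIIIIII
@rna_12
AAAAATTTTT
+
IIIIIIIIII
@rna_13
AAAAAAAAA
+
IIIIIIIII
@rna_14
AAAAACCCCC
+
IIIIIIIIII
@rna_15
AAAAAGGGGG
+
IIIIIIIIII
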