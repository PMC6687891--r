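@dna_01
AAAAACCCCC
+
IIIIIIIIII
@dna_02
AAAAAGGGGG
+
IIIIIIIIII
@dna_03
AAAAATTTTT
+
IIIIIIIIII
@dna_04
AAAAACCCCC
+
IIIIIIIIII
@dna_05
AAAAACCCCC
+
IIIIIIIIII
@dna_06
AAAAACCCCC
+
IIIIIIIIII
@dna_07
AAAAAGGGGG
+
IIIIIIIIII
@dna_08
AAAAACCCCC
+
IIIIIIIIII
@dna_09
AAAAACCCCC
+
IIIIIIIIII
@dna_10
AAAAACCCCC
+
IIIIIIIIII
@dna_11
AAAAACCCCC
+
IIIIIIIIII
@dna_12
NAAAAAAAAA
+
IIIIIIIIII
@dna_13
AAAAAAAAA
+
IIIIIIIII
@dna_14
AAAAACCCCC
+
IIIIIIIIII
@dna_15
AAAAAGGGGG
+
IIIIIIIIII
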