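# SYNTHETIC idealized helix table for E. coli 5S rRNA, 120 nt.
# The consensus secondary structure (helices I-V, loops A-E; cf. PDB 1C2X
# chain C) contains bulged helices that a model restricted to ungapped
# duplexes cannot represent; this encoding absorbs the bulges into five
# ungapped helices while preserving the overall organization: terminal
# helix I (alpha domain), helix II + internal loop B + helix III with
# hairpin loop C (beta domain), helix IV + internal loop E + helix V with
# hairpin loop D (gamma domain), all joined at one hinge (loop A).
# 86 of 120 nucleotides paired.
# n_residues: 120
name	a_start	a_end	b_start	b_end
I	1	10	111	120
II	16	25	56	65
III	30	36	42	48
IV	70	77	103	110
V	80	87	93	100
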