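# Yeast tRNA-Phe cloverleaf topology, 76 nt (cf. PDB 1EHZ numbering):
# acceptor stem 7 bp, D stem 4 bp, anticodon stem 5 bp, T stem 5 bp;
# four helices, three hairpin loops, one central hinge, 3' ACCA tail.
# n_residues: 76
name	a_start	a_end	b_start	b_end
acceptor	1	7	66	72
D	10	13	22	25
anticodon	27	31	39	43
T	49	53	61	65
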