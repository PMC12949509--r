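code	alt	source	atoms	bonds	loops	undefined	note
C1a	1	kegg	1:C:3;2:*	1-2:s	-	0	methyl R-CH3
C1b	1	kegg	1:C:2;2:*;3:*	1-2:s;1-3:s	-	0	methylene R-CH2-R
C1c	1	kegg	1:C:1;2:*;3:*;4:*	1-2:s;1-3:s;1-4:s	-	0	methine R3-CH
C1d	1	kegg	1:C:0;2:*;3:*;4:*;5:*	1-2:s;1-3:s;1-4:s;1-5:s	-	0	quaternary carbon
C1x	1	kegg	1:C:2;2:*;3:*	1-2:s:r;1-3:s:r	-	0	ring CH2
C1y	1	kegg	1:C:1;2:*;3:*;4:*	1-2:s:r;1-3:s:r;1-4:s	-	0	ring CH, exocyclic substituent
C1y	2	inferred	1:C:1;2:*;3:*;4:*	1-2:s:r;1-3:s:r;1-4:s:r	-	0	ring CH at a ring fusion
C1z	1	kegg	1:C:0;2:*;3:*;4:*;5:*	1-2:s:r;1-3:s:r;1-4:s;1-5:s	-	0	ring quaternary carbon
C1z	2	inferred	1:C:0;2:*;3:*;4:*;5:*	1-2:s:r;1-3:s:r;1-4:s:r;1-5:s:r	-	0	spiro/fused ring quaternary carbon
C2a	1	kegg	1:C:2;2:*	1-2:d	-	0	terminal methylene CH2=
C2b	1	kegg	1:C:1;2:*;3:*	1-2:d;1-3:s	-	0	vinylic CH, R-CH=R
C2c	1	kegg	1:C:0;2:*;3:*;4:*	1-2:d;1-3:s;1-4:s	-	0	substituted vinylic carbon
C2c	2	inferred	1:C:0;2:*;3:*;4:*	1-2:d;1-3:s:r;1-4:s:r	-	0	exocyclic double bond off a ring atom
C2x	1	kegg	1:C:1;2:*;3:*	1-2:d:r;1-3:s:r	-	0	ring vinylic CH
C2x	2	inferred	1:C:1;2:*;3:*	1-2:d:r;1-3:s	-	0	ring vinylic CH at ring border
C2y	1	kegg_documented	1:C:0;2:*;3:*;4:*	1-2:d:r;1-3:s:r;1-4:s	-	0	ring vinylic carbon, exocyclic substituent
C2y	2	kegg_documented	1:C:0;2:*;3:*;4:*	1-2:d:r;1-3:s:r;1-4:s:r	-	0	ring vinylic carbon at a ring fusion
C2z	1	kegg	1:C:0;2:*;3:*	1-2:d;1-3:d	-	0	cumulated sp carbon R=C=R
C2z	2	inferred	1:C:0;2:*;3:O:0	1-2:d;1-3:d	-	0	ketene-like cumulated carbon
C3a	1	kegg	1:C:1;2:*	1-2:t	-	0	terminal alkyne CH
C3b	1	kegg	1:C:0;2:*;3:*	1-2:t;1-3:s	-	0	internal alkyne carbon
C4a	1	kegg	1:C:1;2:O:0;3:*	1-2:d;1-3:s	-	0	aldehyde carbon R-CHO
C5a	1	kegg	1:C:0;2:O:0;3:*;4:*	1-2:d;1-3:s;1-4:s	-	0	ketone carbon
C5a	2	inferred	1:C:0;2:O:1;3:*;4:*	1-2:s;1-3:d;1-4:s	-	0	enol tautomer of the ketone carbon
C5x	1	kegg	1:C:0;2:O:0;3:*;4:*	1-2:d;1-3:s:r;1-4:s:r	-	0	ring ketone carbon
C6a	1	kegg	1:C:0;2:O:0;3:O:1;4:*	1-2:d;1-3:s;1-4:s	-	0	carboxy carbon R-COOH
C6a	2	inferred	1:C:0;2:O:0;3:O:0;4:*	1-2:d;1-3:s;1-4:s	3=charge:-1	0	carboxylate carbon R-COO-
C7a	1	kegg	1:C:0;2:O:0;3:O:0;4:*	1-2:d;1-3:s;1-4:s	-	0	ester carbon
C7a	2	inferred	1:C:0;2:O:0;3:S:0;4:*	1-2:d;1-3:s;1-4:s	-	0	thioester carbon
C7x	1	kegg	1:C:0;2:O:0;3:O:0;4:*	1-2:d;1-3:s:r;1-4:s:r	-	0	lactone carbon
C8x	1	kegg	1:C:1;2:*;3:*	1-2:a:r;1-3:a:r	-	0	aromatic CH
C8y	1	kegg	1:C:0;2:*;3:*;4:*	1-2:a:r;1-3:a:r;1-4:s	-	0	substituted aromatic carbon
C8y	2	inferred	1:C:0;2:*;3:*;4:*	1-2:a:r;1-3:a:r;1-4:a:r	-	0	aromatic carbon at a ring fusion
N1a	1	kegg_documented	1:N:2;2:*	1-2:s	-	0	primary amine R-NH2
N1a	2	kegg_documented	1:N:3;2:*	1-2:s	1=charge:+1	0	ammonium R-NH3+
N1b	1	kegg_documented	1:N:1;2:*;3:*	1-2:s;1-3:s	-	0	secondary amine
N1b	2	kegg_documented	1:N:2;2:*;3:*	1-2:s;1-3:s	1=charge:+1	0	protonated secondary amine
N1c	1	kegg_documented	1:N:0;2:*;3:*;4:*	1-2:s;1-3:s;1-4:s	-	0	tertiary amine
N1c	2	kegg_documented	1:N:1;2:*;3:*;4:*	1-2:s;1-3:s;1-4:s	1=charge:+1	0	protonated tertiary amine
N1d	1	kegg	1:N:0;2:*;3:*;4:*;5:*	1-2:s;1-3:s;1-4:s;1-5:s	1=charge:+1	0	quaternary ammonium
N1d	2	inferred	1:N:0;2:*;3:*;4:*;5:*	1-2:s;1-3:s;1-4:s;1-5:s	-	0	quaternary N, charge left implicit
N1x	1	kegg	1:N:1;2:*;3:*	1-2:s:r;1-3:s:r	-	0	ring NH
N1y	1	kegg	1:N:0;2:*;3:*;4:*	1-2:s:r;1-3:s:r;1-4:s	-	0	substituted ring N
N2a	1	kegg_documented	1:N:1;2:*	1-2:d	-	0	imine NH=
N2a	2	kegg_documented	1:N:2;2:*	1-2:d	1=charge:+1	0	iminium NH2+=
N2b	1	kegg	1:N:0;2:*;3:*	1-2:d;1-3:s	-	0	substituted imine N
N2b	2	inferred	1:N:1;2:*;3:*	1-2:d;1-3:s	1=charge:+1	0	protonated substituted imine N
N2x	1	kegg	1:N:0;2:*;3:*	1-2:d:r;1-3:s:r	-	0	ring imine N
N2x	2	inferred	1:N:0;2:*;3:*	1-2:d:r;1-3:s	-	0	ring imine N at ring border
N2y	1	kegg	1:N:0;2:*;3:*;4:*	1-2:d:r;1-3:s:r;1-4:s	1=charge:+1	0	ring iminium N+
N3a	1	kegg	1:N:0;2:*	1-2:t	-	0	nitrile N
N4x	1	kegg	1:N:1;2:*;3:*	1-2:a:r;1-3:a:r	-	0	aromatic NH (pyrrole-type)
N4y	1	kegg	1:N:0;2:*;3:*;4:*	1-2:a:r;1-3:a:r;1-4:s	-	0	substituted aromatic N
N4y	2	inferred	1:N:0;2:*;3:*;4:*	1-2:a:r;1-3:a:r;1-4:a:r	-	0	aromatic N at a ring fusion
N5x	1	kegg	1:N:0;2:*;3:*	1-2:a:r;1-3:a:r	-	0	aromatic N (pyridine-type)
N5x	2	inferred	1:N:0;2:O:0;3:*;4:*	1-2:s;1-3:a:r;1-4:a:r	1=charge:+1;2=charge:-1	0	aromatic N-oxide
N5y	1	kegg	1:N:0;2:*;3:*;4:*	1-2:a:r;1-3:a:r;1-4:s	1=charge:+1	0	aromatic N+ (pyridinium-type)
N0	1	kegg	1:N:0;2:O:0;3:O:0;4:*	1-2:d;1-3:s;1-4:s	-	0	nitro-type nitrogen
O1a	1	kegg	1:O:1;2:*	1-2:s	-	0	hydroxyl R-OH
O1a	2	inferred	1:O:0;2:*	1-2:s	1=charge:-1	0	alkoxide R-O-
O1b	1	kegg	1:O:1;2:C:0;3:*;4:*	1-2:s;2-3:a:r;2-4:a:r	-	0	phenolic OH
O1c	1	kegg	1:O:1;2:P:0	1-2:s	-	0	phosphate hydroxyl H-O-P
O1d	1	kegg	1:O:1;2:S:0	1-2:s	-	0	sulfate hydroxyl H-O-S
O2a	1	kegg	1:O:0;2:*;3:*	1-2:s;1-3:s	-	0	ether R-O-R
O2b	1	kegg	1:O:0;2:P:0;3:*	1-2:s;1-3:s	-	0	phosphoester bridge P-O-C
O2c	1	kegg	1:O:0;2:P:0;3:P:0	1-2:s;1-3:s	-	0	diphosphate bridge P-O-P
O2x	1	kegg	1:O:0;2:*;3:*	1-2:s:r;1-3:s:r	-	0	ring ether O
O3a	1	kegg	1:O:0;2:S:0;3:*	1-2:s;1-3:s	-	0	sulfoester bridge S-O-C
O3c	1	kegg	1:O:0;2:S:0;3:S:0	1-2:s;1-3:s	-	0	S-O-S bridge
O4a	1	kegg	1:O:0;2:C:1;3:*	1-2:d;2-3:s	-	0	aldehyde oxygen
O5a	1	kegg	1:O:0;2:C:0;3:*;4:*	1-2:d;2-3:s;2-4:s	-	0	ketone oxygen
O5a	2	inferred	1:O:1;2:C:0;3:*	1-2:s;2-3:d	-	0	enol tautomer of the ketone oxygen
O5x	1	kegg	1:O:0;2:C:0;3:*;4:*	1-2:d;2-3:s:r;2-4:s:r	-	0	ring ketone oxygen
O6a	1	kegg	1:O:0;2:C:0;3:O:1;4:*	1-2:d;2-3:s;2-4:s	-	0	carboxy oxygen (of R-COOH)
O6a	2	inferred	1:O:0;2:C:0;3:O:0;4:*	1-2:s;2-3:d;2-4:s	1=charge:-1	0	carboxylate oxygen (of R-COO-)
O7a	1	kegg	1:O:0;2:C:0;3:O:0;4:*	1-2:d;2-3:s;2-4:s	-	0	ester carbonyl oxygen
O7x	1	kegg	1:O:0;2:C:0;3:O:0;4:*	1-2:d;2-3:s:r;2-4:s:r	-	0	lactone carbonyl oxygen
O0	1	kegg	1:O:2	-	-	0	water / isolated oxygen
O0	2	inferred	1:O:1	-	1=charge:-1	0	hydroxide ion
S1a	1	kegg	1:S:1;2:*	1-2:s	-	0	thiol R-SH
S2a	1	kegg	1:S:0;2:*;3:*	1-2:s;1-3:s	-	0	thioether R-S-R
S2a	2	inferred	1:S:0;2:*;3:*;4:*	1-2:s;1-3:s;1-4:s	1=charge:+1	0	sulfonium R3-S+
S2x	1	kegg	1:S:0;2:*;3:*	1-2:s:r;1-3:s:r	-	0	ring thioether S
S3a	1	kegg	1:S:0;2:S:0;3:*	1-2:s;1-3:s	-	0	disulfide S
S3x	1	kegg	1:S:0;2:S:0;3:*	1-2:s:r;1-3:s:r	-	0	ring disulfide S
S4a	1	kegg	1:S:0;2:O:0;3:*;4:*	1-2:d;1-3:s;1-4:s	-	0	sulfoxide S
S6a	1	kegg	1:S:0;2:O:0;3:O:0;4:O:1;5:*	1-2:d;1-3:d;1-4:s;1-5:s	-	0	sulfonate S
S0	1	kegg	1:S:0	-	-	0	isolated sulfur
P1a	1	inferred	1:P:0;2:*	1-2:s	-	0	P-R
P1a	2	inferred	1:P:0;2:*;3:*;4:*;5:*	1-2:s;1-3:s;1-4:s;1-5:d	-	0	R-P(-R)(-R)(=R)
P1a	3	inferred	1:P:0;2:*;3:O:0;4:*	1-2:s;1-3:s;1-4:d	-	0	R-P(-O)(=R)
P1a	4	inferred	1:P:0;2:*;3:*	1-2:s:r;1-3:s:r	-	0	R-ring-P-ring-R
P1b	1	kegg	1:P:0;2:O:0	1-2:s	-	0	P-O
X	1	kegg	1:X:0;2:*	1-2:s	-	0	halogen (F, Cl, Br, I)
Z	1	kegg	1:Z:0	-	-	1	undefined atom (non-convertible)
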