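# Per-residue physicochemical properties (one row per standard amino acid).
# Sources: AAIndex accessions KLEP840101 (net charge), FAUJ880109+FAUJ880110
# (hydrogen-bond donors + acceptor orbitals), KYTJ820101 (hydropathy),
# HOPT810101 (hydrophilicity), WERD780101 (burial propensity), ZIMJ680104
# (isoelectric point), FASG760101 (molecular weight), NISK860101 (14 A contact
# number), VELV850101 (electron-ion interaction potential); n_atoms counted
# from the molecular formula of the free amino acid.
amino_acid	n_atoms	net_charge	h_bond_capacity	hydrophobicity	hydrophilicity	burial_propensity	isoelectric_point	mass	contacts_14A	eiip
A	13	0	0	1.8	-0.5	0.52	6	89.09	-0.22	0.03731
C	14	0	0	2.5	-1	0.83	5.05	121.15	4.66	0.08292
D	16	-1	5	-3.5	3	0.37	2.77	133.1	-4.12	0.1263
E	19	-1	5	-3.5	3	0.38	3.22	147.13	-3.64	0.0058
F	23	0	0	2.8	-2.5	0.87	5.48	165.19	5.27	0.0946
G	10	0	0	-0.4	0	0.41	5.97	75.07	-1.62	0.00499
H	20	0	2	-3.2	-0.5	0.7	7.59	155.16	1.28	0.02415
I	22	0	0	4.5	-1.8	0.79	6.02	131.17	5.58	0
K	24	1	3	-3.9	3	0.31	9.74	146.19	-4.18	0.0371
L	22	0	0	3.8	-1.8	0.77	5.98	131.17	5.01	0
M	20	0	0	1.9	-1.3	0.76	5.74	149.21	3.51	0.08226
N	17	0	5	-3.5	0.2	0.42	5.41	132.12	-2.65	0.00359
P	17	0	0	-1.6	0	0.35	6.3	115.13	-3.03	0.01979
Q	20	0	5	-3.5	0.2	0.35	5.65	146.15	-2.76	0.07606
R	26	1	7	-4.5	3	0.49	10.76	174.2	-0.93	0.09593
S	14	0	3	-0.8	0.3	0.49	5.68	105.09	-2.84	0.08292
T	17	0	3	-0.7	-0.4	0.38	5.66	119.12	-1.2	0.09408
V	19	0	0	4.2	-1.5	0.72	5.96	117.15	4.45	0.00569
W	27	0	1	-0.9	-3.4	0.86	5.89	204.24	5.2	0.05481
Y	24	0	3	-1.3	-2.3	0.64	5.66	181.19	2.15	0.05159
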