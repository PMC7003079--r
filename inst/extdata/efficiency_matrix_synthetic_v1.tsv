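# name: efficiency_matrix_synthetic_v1
# Synthetic default position-weight matrix for protospacer efficiency
# scoring. Positions are counted 1..20 from the PAM-distal end (20 is the
# base adjacent to the PAM). Weights encode broad literature-style
# tendencies (G favored PAM-proximal, T disfavored 3') but are NOT fitted
# to experimental cleavage data; supply your own matrix for real campaigns.
position	A	C	G	T
1	0.02	-0.01	0.03	-0.02
2	0.01	0.00	0.02	-0.01
3	-0.02	0.03	0.01	-0.01
4	0.00	0.02	0.04	-0.03
5	0.03	-0.02	0.02	-0.01
6	-0.01	0.01	0.05	-0.04
7	0.02	0.00	0.03	-0.02
8	-0.03	0.04	0.02	-0.01
9	0.01	0.02	0.06	-0.05
10	0.00	-0.01	0.04	-0.02
11	0.02	0.03	0.05	-0.04
12	-0.02	0.01	0.07	-0.03
13	0.01	0.04	0.06	-0.05
14	0.03	0.02	0.08	-0.06
15	-0.01	0.05	0.09	-0.07
16	0.02	0.03	0.10	-0.08
17	0.04	0.06	0.12	-0.10
18	0.01	0.05	0.14	-0.12
19	0.03	0.08	0.16	-0.14
20	0.05	0.10	0.20	-0.18
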