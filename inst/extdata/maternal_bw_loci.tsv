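# Ten maternal loci associated with offspring birth weight at genome-wide
# significance in a European-ancestry meta-analysis of up to 86 577 women.
# Effects are per birth weight-raising allele, in SD units of birth weight
# (1 SD = 484 g).
locus	snp_id	chr	pos_b37	effect_allele	other_allele	eaf	beta	se	n
MTNR1B	rs10830963	11	92708710	G	C	0.29	0.052	0.006	71341
HMGA2	rs1351394	12	66351826	T	C	0.49	0.034	0.005	68247
SH2B3	rs3184504	12	111884608	C	T	0.52	0.033	0.005	68249
KCNAB1	rs7629460	3	155829938	C	A	0.59	0.039	0.007	48632
L3MBTL3	rs9375694	6	130356608	G	A	0.31	0.035	0.006	68223
GCK	rs2971669	7	44231778	T	C	0.23	0.038	0.007	68162
EBF1	rs12520982	5	157894747	T	C	0.74	0.041	0.007	48632
TCF7L2	rs7903146	10	114758349	T	C	0.30	0.034	0.006	68253
ACTL9	rs2918299	19	8787273	C	T	0.83	0.041	0.007	67603
CYP3A7	rs45446698	7	99332948	G	T	0.04	0.089	0.016	48632
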