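! total_genes: NA
term	ic
GO:0006139	1.61699999999999999
GO:0008150	0.00000000000000000
GO:0008152	1.09800000000000009
GO:0009987	0.40699999999999997
GO:0034641	1.99900000000000011
GO:0043170	2.08599999999999985
GO:0044237	1.32899999999999996
GO:0044238	1.47900000000000009
GO:0044260	2.15799999999999992
GO:0044262	1.69999999999999996
GO:0071704	1.25499999999999989
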