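!gaf-version: 2.2
SYNT	GENE01	GENE01		GO:0034641	SYNT:0000001	IDA		P	GENE01		protein	taxon:0000	20260101	SYNT		
SYNT	GENE01	GENE01		GO:0044237	SYNT:0000001	EXP		P	GENE01		protein	taxon:0000	20260101	SYNT		
SYNT	GENE02	GENE02		GO:0009987	SYNT:0000001	IEA		P	GENE02		protein	taxon:0000	20260101	SYNT		
SYNT	GENE02	GENE02		GO:0034641	SYNT:0000001	IEA		P	GENE02		protein	taxon:0000	20260101	SYNT		
SYNT	GENE03	GENE03		GO:0006139	SYNT:0000001	IDA		P	GENE03		protein	taxon:0000	20260101	SYNT		
SYNT	GENE03	GENE03		GO:0043170	SYNT:0000001	IDA		P	GENE03		protein	taxon:0000	20260101	SYNT		
SYNT	GENE04	GENE04		GO:0006139	SYNT:0000001	IEA		P	GENE04		protein	taxon:0000	20260101	SYNT		
SYNT	GENE04	GENE04		GO:0008152	SYNT:0000001	EXP		P	GENE04		protein	taxon:0000	20260101	SYNT		
SYNT	GENE04	GENE04		GO:0034641	SYNT:0000001	EXP		P	GENE04		protein	taxon:0000	20260101	SYNT		
SYNT	GENE05	GENE05		GO:0043170	SYNT:0000001	IDA		P	GENE05		protein	taxon:0000	20260101	SYNT		
SYNT	GENE05	GENE05		GO:0044260	SYNT:0000001	EXP		P	GENE05		protein	taxon:0000	20260101	SYNT		
SYNT	GENE06	GENE06		GO:0008152	SYNT:0000001	IDA		P	GENE06		protein	taxon:0000	20260101	SYNT		
SYNT	GENE06	GENE06		GO:0044237	SYNT:0000001	IDA		P	GENE06		protein	taxon:0000	20260101	SYNT		
SYNT	GENE06	GENE06		GO:0044260	SYNT:0000001	IEA		P	GENE06		protein	taxon:0000	20260101	SYNT		
SYNT	GENE07	GENE07		GO:0044237	SYNT:0000001	EXP		P	GENE07		protein	taxon:0000	20260101	SYNT		
SYNT	GENE07	GENE07		GO:0044238	SYNT:0000001	IDA		P	GENE07		protein	taxon:0000	20260101	SYNT		
SYNT	GENE07	GENE07		GO:0044260	SYNT:0000001	IEA		P	GENE07		protein	taxon:0000	20260101	SYNT		
SYNT	GENE08	GENE08		GO:0044237	SYNT:0000001	IDA		P	GENE08		protein	taxon:0000	20260101	SYNT		
SYNT	GENE08	GENE08		GO:0044260	SYNT:0000001	EXP		P	GENE08		protein	taxon:0000	20260101	SYNT		
SYNT	GENE08	GENE08		GO:0044262	SYNT:0000001	IEA		P	GENE08		protein	taxon:0000	20260101	SYNT		
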