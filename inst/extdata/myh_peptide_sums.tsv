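sample_id	protein_group	peptide_sequence	proteotypic	intensity
I	MYH7	DTQIQLDDAVR	TRUE	226.57
I	MYH7	IEDEQALGSQLQK	TRUE	162.65
I	MYH7	ANDDLKENIAIVER	TRUE	137.41
I	MYH7	GQNVQQVSYAIGALAK	TRUE	80.46
I	MYH7	SLQSLLK	TRUE	74.67
I	MYH2	LINDLTTQR	TRUE	95.23
I	MYH2	AAYLQGLNSADLLK	TRUE	77.60
I	MYH2	VLNASAIPEGQYIDSK	TRUE	74.62
I	MYH2	GQTVEQVTNAVGALAK	TRUE	39.80
I	MYH2	IEDEQAIGIQLQK	TRUE	25.58
I	MYH4	VAEQELLDASER	TRUE	3.78
I	MYH4	LINELSTQK	TRUE	4.17
I	MYH4	AAYLTSLNSADLLK	TRUE	1.87
I	MYH4	LQDAEEHVEAVNSK	TRUE	1.42
I	MYH4	RVAEQELLDASER	TRUE	1.52
I	MYH1	AAYLQNLNSADLLK	TRUE	14.02
I	MYH1	SALAHALQSSR	TRUE	14.19
I	MYH1	DSLVSQLSR	TRUE	8.37
I	MYH1	NAYEESLDHLETLKR	TRUE	4.60
I	MYH1	QLDEKDSLVSQLSR	TRUE	4.59
IIa	MYH7	DTQIQLDDAVR	TRUE	45.22
IIa	MYH7	IEDEQALGSQLQK	TRUE	34.33
IIa	MYH7	ANDDLKENIAIVER	TRUE	27.70
IIa	MYH7	GQNVQQVSYAIGALAK	TRUE	15.95
IIa	MYH7	SLQSLLK	TRUE	15.45
IIa	MYH2	LINDLTTQR	TRUE	216.18
IIa	MYH2	AAYLQGLNSADLLK	TRUE	179.82
IIa	MYH2	VLNASAIPEGQYIDSK	TRUE	173.66
IIa	MYH2	GQTVEQVTNAVGALAK	TRUE	106.67
IIa	MYH2	IEDEQAIGIQLQK	TRUE	71.06
IIa	MYH4	VAEQELLDASER	TRUE	3.82
IIa	MYH4	LINELSTQK	TRUE	4.55
IIa	MYH4	AAYLTSLNSADLLK	TRUE	2.98
IIa	MYH4	LQDAEEHVEAVNSK	TRUE	1.34
IIa	MYH4	RVAEQELLDASER	TRUE	2.48
IIa	MYH1	AAYLQNLNSADLLK	TRUE	20.54
IIa	MYH1	SALAHALQSSR	TRUE	20.28
IIa	MYH1	DSLVSQLSR	TRUE	11.42
IIa	MYH1	NAYEESLDHLETLKR	TRUE	6.71
IIa	MYH1	QLDEKDSLVSQLSR	TRUE	6.82
IIb	MYH7	DTQIQLDDAVR	TRUE	0.00
IIb	MYH7	IEDEQALGSQLQK	TRUE	0.05
IIb	MYH7	ANDDLKENIAIVER	TRUE	0.01
IIb	MYH7	GQNVQQVSYAIGALAK	TRUE	0.04
IIb	MYH7	SLQSLLK	TRUE	0.02
IIb	MYH2	LINDLTTQR	TRUE	8.32
IIb	MYH2	AAYLQGLNSADLLK	TRUE	8.17
IIb	MYH2	VLNASAIPEGQYIDSK	TRUE	6.23
IIb	MYH2	GQTVEQVTNAVGALAK	TRUE	3.76
IIb	MYH2	IEDEQAIGIQLQK	TRUE	2.53
IIb	MYH4	VAEQELLDASER	TRUE	221.71
IIb	MYH4	LINELSTQK	TRUE	175.11
IIb	MYH4	AAYLTSLNSADLLK	TRUE	129.68
IIb	MYH4	LQDAEEHVEAVNSK	TRUE	75.10
IIb	MYH4	RVAEQELLDASER	TRUE	74.18
IIb	MYH1	AAYLQNLNSADLLK	TRUE	25.48
IIb	MYH1	SALAHALQSSR	TRUE	17.76
IIb	MYH1	DSLVSQLSR	TRUE	13.79
IIb	MYH1	NAYEESLDHLETLKR	TRUE	8.68
IIb	MYH1	QLDEKDSLVSQLSR	TRUE	8.77
IIx	MYH7	DTQIQLDDAVR	TRUE	0.00
IIx	MYH7	IEDEQALGSQLQK	TRUE	0.19
IIx	MYH7	ANDDLKENIAIVER	TRUE	0.01
IIx	MYH7	GQNVQQVSYAIGALAK	TRUE	0.03
IIx	MYH7	SLQSLLK	TRUE	0.03
IIx	MYH2	LINDLTTQR	TRUE	14.98
IIx	MYH2	AAYLQGLNSADLLK	TRUE	11.76
IIx	MYH2	VLNASAIPEGQYIDSK	TRUE	11.20
IIx	MYH2	GQTVEQVTNAVGALAK	TRUE	7.45
IIx	MYH2	IEDEQAIGIQLQK	TRUE	5.65
IIx	MYH4	VAEQELLDASER	TRUE	49.27
IIx	MYH4	LINELSTQK	TRUE	37.76
IIx	MYH4	AAYLTSLNSADLLK	TRUE	24.67
IIx	MYH4	LQDAEEHVEAVNSK	TRUE	17.27
IIx	MYH4	RVAEQELLDASER	TRUE	19.12
IIx	MYH1	AAYLQNLNSADLLK	TRUE	122.96
IIx	MYH1	SALAHALQSSR	TRUE	97.12
IIx	MYH1	DSLVSQLSR	TRUE	49.63
IIx	MYH1	NAYEESLDHLETLKR	TRUE	41.85
IIx	MYH1	QLDEKDSLVSQLSR	TRUE	41.53
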