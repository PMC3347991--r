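category	key1	key2	value
stack	AU	AU	-0.93
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	UA	-1.1
stack	AU	GU	-0.8
stack	AU	UG	-0.8
stack	CG	AU	-2.11
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	UA	-2.08
stack	CG	GU	-1.5
stack	CG	UG	-1.5
stack	GC	AU	-2.35
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	UA	-2.24
stack	GC	GU	-1.5
stack	GC	UG	-1.5
stack	UA	AU	-1.33
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	UA	-0.93
stack	UA	GU	-0.8
stack	UA	UG	-0.8
stack	GU	AU	-0.8
stack	GU	CG	-1.5
stack	GU	GC	-1.5
stack	GU	UA	-0.8
stack	GU	GU	-0.5
stack	GU	UG	-0.5
stack	UG	AU	-0.8
stack	UG	CG	-1.5
stack	UG	GC	-1.5
stack	UG	UA	-0.8
stack	UG	GU	-0.5
stack	UG	UG	-0.5
hairpin	3		5.4
hairpin	4		5.6
hairpin	5		5.7
hairpin	6		5.4
hairpin	7		6
hairpin	8		5.6
hairpin	9		6.4
hairpin	10		6.5
hairpin	11		6.6
hairpin	12		6.7
hairpin	13		6.8
hairpin	14		6.9
hairpin	15		7
hairpin	16		7
hairpin	17		7.1
hairpin	18		7.1
hairpin	19		7.2
hairpin	20		7.3
hairpin	21		7.3
hairpin	22		7.4
hairpin	23		7.4
hairpin	24		7.5
hairpin	25		7.5
hairpin	26		7.5
hairpin	27		7.6
hairpin	28		7.6
hairpin	29		7.7
hairpin	30		7.7
bulge	1		3.8
bulge	2		2.8
bulge	3		3.2
bulge	4		3.6
bulge	5		4
bulge	6		4.4
bulge	7		4.6
bulge	8		4.7
bulge	9		4.8
bulge	10		5
bulge	11		5.1
bulge	12		5.1
bulge	13		5.2
bulge	14		5.3
bulge	15		5.4
bulge	16		5.5
bulge	17		5.5
bulge	18		5.6
bulge	19		5.6
bulge	20		5.7
bulge	21		5.8
bulge	22		5.8
bulge	23		5.9
bulge	24		5.9
bulge	25		5.9
bulge	26		6
bulge	27		6
bulge	28		6.1
bulge	29		6.1
bulge	30		6.1
internal	2		1
internal	3		1.6
internal	4		1.7
internal	5		2
internal	6		2.2
internal	7		2.4
internal	8		2.5
internal	9		2.6
internal	10		2.8
internal	11		2.9
internal	12		2.9
internal	13		3
internal	14		3.1
internal	15		3.2
internal	16		3.3
internal	17		3.3
internal	18		3.4
internal	19		3.4
internal	20		3.5
internal	21		3.6
internal	22		3.6
internal	23		3.7
internal	24		3.7
internal	25		3.7
internal	26		3.8
internal	27		3.8
internal	28		3.9
internal	29		3.9
internal	30		3.9
param	ml_closing		3.4
param	ml_branch		0.4
param	ml_unpaired		0.1
param	loop_ln_coef		1.08
param	max_interior_loop		30
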