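# Synthetic demo germline locus table (invented sequences, valid structure).
# position: 5'->3' rank P within (locus, segment); 1 = most distal/upstream.
# boundaries: comma-separated 0-based half-open offsets. V genes:
#   fr1_start,fr1_end,cdr1_start,cdr1_end,fr2_start,fr2_end,cdr2_start,
#   cdr2_end,fr3_start,fr3_end (FR3 ends after the conserved Cys codon).
# J genes: anchor_start,anchor_end of the conserved Trp (heavy) / Phe
# (light) codon. Empty for D and C genes.
name	locus	segment	family	position	boundaries
IGHV3-74*01	IGH	V	IGHV3	1	0,78,78,102,102,153,153,177,177,297
IGHV4-61*01	IGH	V	IGHV4	2	0,78,78,102,102,153,153,177,177,297
IGHV4-59*01	IGH	V	IGHV4	3	0,78,78,102,102,153,153,177,177,297
IGHV1-46*01	IGH	V	IGHV1	4	0,78,78,102,102,153,153,177,177,297
IGHV3-33*01	IGH	V	IGHV3	5	0,78,78,102,102,153,153,177,177,297
IGHV4-34*01	IGH	V	IGHV4	6	0,78,78,102,102,153,153,177,177,297
IGHV3-23*01	IGH	V	IGHV3	7	0,78,78,102,102,153,153,177,177,297
IGHV1-18*01	IGH	V	IGHV1	8	0,78,78,102,102,153,153,177,177,297
IGHV4-4*01	IGH	V	IGHV4	9	0,78,78,102,102,153,153,177,177,297
IGHV6-1*01	IGH	V	IGHV6	10	0,78,78,102,102,153,153,177,177,297
IGHD1-26*01	IGH	D	IGHD1	1	
IGHD2-15*01	IGH	D	IGHD2	2	
IGHD3-10*01	IGH	D	IGHD3	3	
IGHD4-17*01	IGH	D	IGHD4	4	
IGHD6-19*01	IGH	D	IGHD6	5	
IGHJ1*01	IGH	J	IGHJ1	1	12,15
IGHJ2*01	IGH	J	IGHJ2	2	12,15
IGHJ3*01	IGH	J	IGHJ3	3	12,15
IGHJ4*02	IGH	J	IGHJ4	4	12,15
IGHJ5*01	IGH	J	IGHJ5	5	12,15
IGHJ6*01	IGH	J	IGHJ6	6	12,15
IGHM	IGH	C	IGHM	1	
IGHD	IGH	C	IGHD	2	
IGHG3	IGH	C	IGHG3	3	
IGHG1	IGH	C	IGHG1	4	
IGHA1	IGH	C	IGHA1	5	
IGHG2	IGH	C	IGHG2	6	
IGHG4	IGH	C	IGHG4	7	
IGHE	IGH	C	IGHE	8	
IGHA2	IGH	C	IGHA2	9	
IGKV1-5*01	IGK	V	IGKV1	1	0,78,78,102,102,153,153,177,177,297
IGKV3-20*01	IGK	V	IGKV3	2	0,78,78,102,102,153,153,177,177,297
IGKV2-28*01	IGK	V	IGKV2	3	0,78,78,102,102,153,153,177,177,297
IGKV4-1*01	IGK	V	IGKV4	4	0,78,78,102,102,153,153,177,177,297
IGLV1-51*01	IGL	V	IGLV1	1	0,78,78,102,102,153,153,177,177,297
IGLV2-23*01	IGL	V	IGLV2	2	0,78,78,102,102,153,153,177,177,297
IGLV2-14*01	IGL	V	IGLV2	3	0,78,78,102,102,153,153,177,177,297
IGLV3-21*01	IGL	V	IGLV3	4	0,78,78,102,102,153,153,177,177,297
IGKJ1*01	IGK	J	IGKJ1	1	10,13
IGKJ4*01	IGK	J	IGKJ4	2	10,13
IGLJ1*01	IGL	J	IGLJ1	1	10,13
IGLJ2*01	IGL	J	IGLJ2	2	10,13
IGLJ3*01	IGL	J	IGLJ3	3	10,13
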