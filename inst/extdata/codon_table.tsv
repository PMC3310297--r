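codon	aa	name
ATG	M	Methionine
GAA	E	Glutamic acid
GAG	E	Glutamic acid
CAA	Q	Glutamine
CAG	Q	Glutamine
GAT	D	Aspartic acid
GAC	D	Aspartic acid
CGT	R	Arginine
CGC	R	Arginine
CGA	R	Arginine
CGG	R	Arginine
AGA	R	Arginine
AGG	R	Arginine
ACT	T	Threonine
ACC	T	Threonine
ACA	T	Threonine
ACG	T	Threonine
AAT	N	Asparagine
AAC	N	Asparagine
CAT	H	Histidine
CAC	H	Histidine
GTT	V	Valine
GTC	V	Valine
GTA	V	Valine
GTG	V	Valine
GGT	G	Glycine
GGC	G	Glycine
GGA	G	Glycine
GGG	G	Glycine
TTA	L	Leucine
TTG	L	Leucine
CTT	L	Leucine
CTC	L	Leucine
CTA	L	Leucine
CTG	L	Leucine
TCT	S	Serine
TCC	S	Serine
TCA	S	Serine
TCG	S	Serine
AGT	S	Serine
AGC	S	Serine
CCT	P	Proline
CCC	P	Proline
CCA	P	Proline
CCG	P	Proline
TTT	F	Phenylalanine
TTC	F	Phenylalanine
ATT	I	Isoleucine
ATC	I	Isoleucine
ATA	I	Isoleucine
TGT	C	Cysteine
TGC	C	Cysteine
GCT	A	Alanine
GCC	A	Alanine
GCA	A	Alanine
GCG	A	Alanine
AAA	K	Lysine
AAG	K	Lysine
TAT	Y	Tyrosine
TAC	Y	Tyrosine
TGG	W	Tryptophan
TAA	*	Stop
TAG	*	Stop
TGA	*	Stop
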