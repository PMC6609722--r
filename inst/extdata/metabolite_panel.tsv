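metabolite_id	display_name	pathway
3OHKY	3-Hydroxykynurenine	tryptophan
5HIAA	5-Hydroxyindoleacetic acid	tryptophan
5HTP	5-Hydroxytryptophan	tryptophan
I3AA	Indole-3-acetic acid	tryptophan
KYN	Kynurenine	tryptophan
5HT	Serotonin	tryptophan
TRP	Tryptophan	tryptophan
4HPAC	4-Hydroxyphenylacetic acid	phenylalanine/tyrosine
4HPLA	4-Hydroxyphenyllactic acid	phenylalanine/tyrosine
4HBAC	4-Hydroxybenzoic acid	phenylalanine/tyrosine
HGA	Homogentisic acid	tyrosine
HVA	Homovanillic acid	tyrosine
MHPG	Methoxy-hydroxyphenyl glycol	tyrosine
TYR	Tyrosine	tyrosine
VMA	Vanillylmandelic acid	tyrosine
G	Guanine	purine
GR	Guanosine	purine
HX	Hypoxanthine	purine
URIC	Uric acid	purine
XAN	Xanthine	purine
PXAN	Paraxanthine	purine
XANTH	Xanthosine	purine
MET	Methionine	one_carbon_gsh
CYS	Cysteine	one_carbon_gsh
SA	Salicylate	other
AMTRP	Alpha-Methyltryptophan	other
I3PA	Indole-3-propionic acid	other
Theophylline	Theophylline	other
ATOCO	Tocopherol-alpha	tocopherol
DTOCO	Tocopherol-delta	tocopherol
GTOCO	Tocopherol-gamma	tocopherol
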