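# synthetic default table: derived by the quasi-chemical pipeline from a synthetic contact library (500000 contacts over 4960 interfaces sampled from a known random table, package seed 20/21); NOT a literature-derived potential
res_i	res_j	u_sc
ALA	ALA	0.5738746603
ALA	ARG	0.31881871
ALA	ASN	-0.07363940691
ALA	ASP	0.01792005141
ALA	CYS	0.04380585959
ALA	GLN	0.6894950377
ALA	GLU	-0.3690365019
ALA	GLY	-0.3108004347
ALA	HIS	-0.403874987
ALA	ILE	0.2914891645
ALA	LEU	0.3449407841
ALA	LYS	0.6392315146
ALA	MET	-0.2799074804
ALA	PHE	-0.2208311683
ALA	PRO	-0.5368432908
ALA	SER	0.1785911
ALA	THR	0.1349937801
ALA	TRP	-0.2043098256
ALA	TYR	-0.2215319657
ALA	VAL	0.5744630635
ARG	ARG	-0.6304057902
ARG	ASN	-0.2475849915
ARG	ASP	-0.5391494268
ARG	CYS	0.2644973913
ARG	GLN	0.08494492061
ARG	GLU	0.4177233941
ARG	GLY	0.9531449231
ARG	HIS	-0.2543273293
ARG	ILE	0.7430618304
ARG	LEU	0.3480075059
ARG	LYS	-0.1457380874
ARG	MET	0.8673387371
ARG	PHE	-0.6248042837
ARG	PRO	-0.3761022286
ARG	SER	0.142001524
ARG	THR	0.3211357742
ARG	TRP	0.4560043511
ARG	TYR	-0.1118665849
ARG	VAL	0.3065694467
ASN	ASN	0.1426521525
ASN	ASP	0.6499421568
ASN	CYS	-0.1346581633
ASN	GLN	-0.04875635607
ASN	GLU	0.3509198923
ASN	GLY	0.1173510152
ASN	HIS	0.4137800712
ASN	ILE	-0.1685906419
ASN	LEU	-0.4055102637
ASN	LYS	0.8063237442
ASN	MET	0.0546143306
ASN	PHE	0.926139704
ASN	PRO	-0.4295841347
ASN	SER	-0.2328656756
ASN	THR	-0.1980594478
ASN	TRP	0.3241122614
ASN	TYR	0.08923171456
ASN	VAL	-0.6067840782
ASP	ASP	-0.6228327141
ASP	CYS	0.9490270942
ASP	GLN	0.1038193286
ASP	GLU	0.7261788421
ASP	GLY	-0.2212250305
ASP	HIS	0.06099661181
ASP	ILE	-0.0448104887
ASP	LEU	-0.5317923475
ASP	LYS	0.4805974027
ASP	MET	-0.03868884741
ASP	PHE	-0.2653418185
ASP	PRO	0.1888334072
ASP	SER	0.206265985
ASP	THR	-0.0347691783
ASP	TRP	0.2445000923
ASP	TYR	-0.02299423655
ASP	VAL	0.3026814106
CYS	CYS	0.2410630341
CYS	GLN	-0.151088121
CYS	GLU	-0.2934585274
CYS	GLY	0.2033355459
CYS	HIS	-0.4048023226
CYS	ILE	-0.2847890838
CYS	LEU	0.3413802669
CYS	LYS	-0.3712842472
CYS	MET	0.6191847663
CYS	PHE	-0.02868219123
CYS	PRO	0.3175086841
CYS	SER	0.5012062238
CYS	THR	0.739500989
CYS	TRP	0.4396745189
CYS	TYR	-0.0936990165
CYS	VAL	-0.8597683823
GLN	GLN	0.1873555399
GLN	GLU	-0.05937296741
GLN	GLY	0.5180232497
GLN	HIS	-0.2325228504
GLN	ILE	-0.1396086554
GLN	LEU	-0.07127841804
GLN	LYS	0.05316029169
GLN	MET	0.5945690631
GLN	PHE	-0.01146000567
GLN	PRO	-0.1506539841
GLN	SER	0.3961825204
GLN	THR	-0.27816138
GLN	TRP	-0.6732935662
GLN	TYR	-0.0353602391
GLN	VAL	0.2642311526
GLU	GLU	-0.4162037625
GLU	GLY	-0.3831551725
GLU	HIS	0.4358317463
GLU	ILE	-0.3770044181
GLU	LEU	-0.08460369085
GLU	LYS	-0.1187425313
GLU	MET	0.9488791046
GLU	PHE	0.9169571871
GLU	PRO	0.09363608424
GLU	SER	0.07759120736
GLU	THR	0.6256145863
GLU	TRP	-0.4126866289
GLU	TYR	0.2055792285
GLU	VAL	-0.4598609108
GLY	GLY	0.7227338734
GLY	HIS	0.7082449367
GLY	ILE	-0.3306540012
GLY	LEU	-0.4071833655
GLY	LYS	0.287727145
GLY	MET	-0.1327513741
GLY	PHE	0.2718337804
GLY	PRO	-0.0341773864
GLY	SER	-0.5776239876
GLY	THR	-0.09276930223
GLY	TRP	-0.05119763567
GLY	TYR	-0.2198186388
GLY	VAL	0.559569397
HIS	HIS	0.06067615551
HIS	ILE	0.2174497716
HIS	LEU	0.04399145783
HIS	LYS	-0.1766827349
HIS	MET	0.3047296188
HIS	PHE	-0.5440851597
HIS	PRO	-0.173199963
HIS	SER	0.01410532704
HIS	THR	0.6714139491
HIS	TRP	-0.4684282731
HIS	TYR	0.8287974941
HIS	VAL	0.2652310767
ILE	ILE	-0.7253370506
ILE	LEU	0.325242044
ILE	LYS	0.4495177106
ILE	MET	0.05217864072
ILE	PHE	0.4669026958
ILE	PRO	-0.08644967065
ILE	SER	0.5145680717
ILE	THR	-0.6511581707
ILE	TRP	0.2238282152
ILE	TYR	0.4795865364
ILE	VAL	0.6839422759
LEU	LEU	0.1058482985
LEU	LYS	0.4115850197
LEU	MET	0.1231874549
LEU	PHE	0.08750902264
LEU	PRO	-0.1798761128
LEU	SER	0.5181145026
LEU	THR	-0.2291370092
LEU	TRP	0.0792562868
LEU	TYR	0.01864519578
LEU	VAL	0.05429395593
LYS	LYS	-0.4905299899
LYS	MET	-0.4947733051
LYS	PHE	-0.5252009477
LYS	PRO	0.7557836202
LYS	SER	-0.2509755
LYS	THR	0.0064824836
LYS	TRP	0.629845521
LYS	TYR	-0.2073471242
LYS	VAL	0.0522821733
MET	MET	0.6294486423
MET	PHE	0.1237393727
MET	PRO	-0.3806319722
MET	SER	-0.5591062996
MET	THR	-0.3345237713
MET	TRP	-0.3556857478
MET	TYR	0.1604113269
MET	VAL	-0.09240897544
PHE	PHE	-0.02771339828
PHE	PRO	0.1860330321
PHE	SER	0.1432163495
PHE	THR	-0.3154565172
PHE	TRP	0.0900504988
PHE	TYR	0.4872569451
PHE	VAL	0.8935865795
PRO	PRO	0.8713419003
PRO	SER	0.01004191435
PRO	THR	0.08055106147
PRO	TRP	0.5179611575
PRO	TYR	-0.0411049388
PRO	VAL	0.6243914179
SER	SER	0.08107686482
SER	THR	0.03280884664
SER	TRP	-0.05831744302
SER	TYR	0.2558481656
SER	VAL	-0.2623247457
THR	THR	0.9443977989
THR	TRP	0.5753812569
THR	TYR	0.299291488
THR	VAL	-0.5151257145
TRP	TRP	0.1421255645
TRP	TYR	-0.5083265331
TRP	VAL	0.1959821363
TYR	TYR	-0.7146826416
TYR	VAL	0.8024320216
VAL	VAL	-0.233004049
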