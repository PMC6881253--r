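protein_id	species	context_seq	motif_start	motif_end	declared_class	evidence_code	kd_molar	measure_ph	measure_temp_K	disorder_call	disorder_avg
p21	H_sapiens	RQTSMTDFYHSKRRL	2	9	pip_degron	B	6.7e-08	7.4	298.15	D	0.95
FEN1	H_sapiens	TQGRLDDFFKVTGSL	2	9	pip_box	B	4.5e-05	7.4	298.15	D	0.62
MSH6	H_sapiens	RQSTLYSFFPKSPAL	2	9	pip_box	B	2.9e-06	7.4	298.15	D	0.88
UNG2_variant	H_sapiens	MIGQKTLYSFFTPSP	4	11	pip_box	B	3.4e-05	7.4	298.15	D	0.74
Spd1	S_pombe	IQGSLMDVGMRVRKS	2	9	pip_degron	B	NA	NA	NA	D	0.91
APIM_peptide	designed	MDRWLVKW	3	7	apim	B	1.1e-05	7.4	298.15	NA	NA
Srs2	S_cerevisiae	ASSQMDIF	1	8	unknown	B*	NA	NA	NA	F	0.32
CAF1	H_sapiens	QARL--PF	1	8	unknown	B	NA	NA	NA	D	0.66
DNA_ligase	S_solfataricus	EKRASDLK	1	8	unknown	B	NA	NA	NA	F	0.41
SYN001	S_cerevisiae	SDRENSASEAFAPKA	4	11	unknown	B	NA	NA	NA	D	0.99
SYN002	D_melanogaster	GDTEAGANNYKNSND	4	11	unknown	CY	NA	NA	NA	D	0.99
SYN003	S_cerevisiae	GDGKGESKEVFTDRS	4	11	unknown	B	NA	NA	NA	D	0.78
SYN004	H_sapiens	NNDATGTGNFHKSSR	4	11	unknown	B	NA	NA	NA	D	0.82
SYN005	S_cerevisiae	KDKSGGAAAVFEGGD	4	11	unknown	C	NA	NA	NA	D	0.98
SYN006	S_cerevisiae	KETSGSGNSFLESPP	4	11	unknown	B	NA	NA	NA	F	0.46
SYN007	H_sapiens	PRNGNKSTNHYNNDS	4	11	unknown	C	NA	NA	NA	D	0.59
SYN008	S_cerevisiae	KSEPKSSGGFLSGGE	4	11	unknown	CY	NA	NA	NA	F	0.38
SYN009	S_pombe	NPSKKTMNEHFGDDG	4	11	unknown	B	NA	NA	NA	F	0.24
SYN010	S_cerevisiae	EKNAETVSAFSSSKT	4	11	unknown	B*	NA	NA	NA	D	0.59
SYN011	S_cerevisiae	NSAENAMSNLFAASP	4	11	unknown	C	NA	NA	NA	D	0.77
SYN012	D_melanogaster	SGDAGKLKEYSTKST	4	11	unknown	C	NA	NA	NA	D	0.68
SYN013	H_sapiens	TGKAKTINDSYPAPE	4	11	unknown	C	NA	NA	NA	D	0.7
SYN014	S_pombe	NKKPSEMGGFHGPES	4	11	unknown	B	NA	NA	NA	F	0.46
SYN015	D_melanogaster	RSKKTKMSSKFEAGN	4	11	unknown	B*	NA	NA	NA	D	0.58
SYN016	H_sapiens	TKAGSKISAYLNEPE	4	11	unknown	CY	NA	NA	NA	D	0.55
SYN017	H_sapiens	GRRSGNMNDAFKTNP	4	11	unknown	B	NA	NA	NA	D	0.86
SYN018	S_cerevisiae	DEAGAEIAEFVKANS	4	11	unknown	B*	NA	NA	NA	D	0.58
SYN019	D_melanogaster	RKGSGNVGGKFRNEG	4	11	unknown	B	NA	NA	NA	D	0.83
SYN020	H_sapiens	GPNSGALGSYLPTRT	4	11	unknown	B*	NA	NA	NA	D	0.54
SYN021	S_pombe	NKGGKSMAGSFTTNG	4	11	unknown	B	NA	NA	NA	D	0.95
SYN022	S_cerevisiae	TEPSKSMEGYKNRTP	4	11	unknown	B	NA	NA	NA	D	0.95
SYN023	H_sapiens	NSEPEKLGSSYSPAT	4	11	unknown	CY	NA	NA	NA	D	0.74
SYN024	S_pombe	PPAPNTMESYKPTGN	4	11	unknown	B*	NA	NA	NA	D	0.57
SYN025	S_cerevisiae	RNNSENMEASFRREP	4	11	unknown	CY	NA	NA	NA	D	0.51
SYN026	S_cerevisiae	ESNQGKLGNYANNSD	4	11	unknown	B	NA	NA	NA	D	0.76
SYN027	D_melanogaster	DKRQAGVTELYTNKN	4	11	unknown	C	NA	NA	NA	D	0.71
SYN028	D_melanogaster	TNTQTKMKGYVGRAK	4	11	unknown	B	NA	NA	NA	D	0.68
SYN029	S_cerevisiae	RNPQETLKGHFGKSD	4	11	unknown	B	NA	NA	NA	F	0.39
SYN030	H_sapiens	DPRQNEIENFLEEDN	4	11	unknown	B	NA	NA	NA	F	0.47
SYN031	S_pombe	ARNQAGMAASFDTAR	4	11	unknown	B	NA	NA	NA	D	0.66
SYN032	S_cerevisiae	GRSQANISNYKNTDT	4	11	unknown	C	NA	NA	NA	F	0.46
SYN033	S_cerevisiae	DSRQAGVKGAFKGKK	4	11	unknown	B	NA	NA	NA	D	0.86
SYN034	H_sapiens	TANQTAMTSVAPDAR	4	11	unknown	CY	NA	NA	NA	D	0.57
SYN035	S_cerevisiae	NGGQTTMKSKLGSDT	4	11	unknown	B*	NA	NA	NA	D	0.51
SYN036	H_sapiens	GDDQTNVNAVANGEA	4	11	unknown	B*	NA	NA	NA	D	0.89
SYN037	S_pombe	SGAQGAITGLVRSAT	4	11	unknown	B	NA	NA	NA	D	0.66
SYN038	S_pombe	DTNQSTIKSSVGRAP	4	11	unknown	B	NA	NA	NA	F	0.4
SYN039	S_pombe	KPTQEALTGKAKKGP	4	11	unknown	B*	NA	NA	NA	D	0.56
SYN040	D_melanogaster	SADQANVSGFFDTPN	4	11	unknown	B	NA	NA	NA	D	0.95
SYN041	D_melanogaster	APDQKGVTDYFEESP	4	11	unknown	B	NA	NA	NA	F	0.32
SYN042	S_pombe	EGKQASLASYYSPRG	4	11	unknown	CY	NA	NA	NA	D	0.56
SYN043	S_cerevisiae	GPTQAKLGNYYTPRN	4	11	unknown	B*	NA	NA	NA	D	0.75
SYN044	S_cerevisiae	TNSQSTVGGFFNRPD	4	11	unknown	B*	NA	NA	NA	D	0.69
SYN045	D_melanogaster	NAPQKELSNYYETPD	4	11	unknown	B	NA	NA	NA	D	1
SYN046	S_cerevisiae	KEAQEAVADFFDPDT	4	11	unknown	B	NA	NA	NA	D	0.97
SYN047	S_cerevisiae	ATTQKAIENYFGEKP	4	11	unknown	B	NA	NA	NA	F	0.27
SYN048	S_pombe	RNRQTELASFYNKPR	4	11	unknown	B*	NA	NA	NA	D	0.9
SYN049	H_sapiens	SRDQKTMKSYFNEAA	4	11	unknown	C	NA	NA	NA	D	0.63
SYN050	D_melanogaster	SGTQTNITAYFKRES	4	11	unknown	B	NA	NA	NA	D	0.72
SYN051	S_pombe	PSGQTEMNSFFRDTG	4	11	unknown	CY	NA	NA	NA	D	0.62
SYN052	S_cerevisiae	ENDQATLGDYFREPT	4	11	unknown	B	NA	NA	NA	D	0.59
SYN053	S_cerevisiae	AAEQESMTNYFGTGS	4	11	unknown	C	NA	NA	NA	F	0.31
SYN054	S_cerevisiae	DSDQKNVEGYYTDAG	4	11	unknown	B	NA	NA	NA	F	0.47
SYN055	D_melanogaster	RRKQENIENFFSTDG	4	11	unknown	B	NA	NA	NA	F	0.23
SYN056	D_melanogaster	SDAQNGLENFYNPTD	4	11	unknown	C	NA	NA	NA	D	0.82
SYN057	S_pombe	GSEQNNLSEYFERRE	4	11	unknown	B	NA	NA	NA	D	0.94
SYN058	S_pombe	NPEQESLSGYYDTRN	4	11	unknown	C	NA	NA	NA	D	0.71
SYN059	S_cerevisiae	NAGQKNMKAYYDKKR	4	11	unknown	B	NA	NA	NA	D	0.84
SYN060	D_melanogaster	PSSQKSVNEFFETST	4	11	unknown	C	NA	NA	NA	D	0.6
SYN061	D_melanogaster	DEGQNAVEDFYSAKK	4	11	unknown	B	NA	NA	NA	D	0.66
SYN062	H_sapiens	PTGQSELNSFYNTSK	4	11	unknown	B	NA	NA	NA	F	0.48
SYN063	S_cerevisiae	ATRQENIEGYYTPTG	4	11	unknown	B	NA	NA	NA	D	0.82
SYN064	H_sapiens	GSNQTTVADFYNDPR	4	11	unknown	B	NA	NA	NA	D	0.68
SYN065	D_melanogaster	TSSQNSLTDFFETTK	4	11	unknown	B	NA	NA	NA	D	0.79
SYN066	S_pombe	ADGQENMGGFFDNGK	4	11	unknown	B	NA	NA	NA	D	0.5
SYN067	D_melanogaster	TGEQTGLEGFYGPDP	4	11	unknown	B	NA	NA	NA	D	0.58
SYN068	D_melanogaster	PNEQTALSEFYTARD	4	11	unknown	B	NA	NA	NA	D	0.78
SYN069	D_melanogaster	ANKQTNINAFFKNSN	4	11	unknown	CY	NA	NA	NA	D	0.57
SYN070	S_pombe	NESQGTMSNFFRPGR	4	11	unknown	B*	NA	NA	NA	F	0.09
SYN071	H_sapiens	GPSQATMKDYYETAK	4	11	unknown	B	NA	NA	NA	D	0.74
SYN072	H_sapiens	SNAQKTITSYYPKDE	4	11	unknown	B	NA	NA	NA	D	0.51
SYN073	D_melanogaster	NTGQSGMENYYTARR	4	11	unknown	B*	NA	NA	NA	D	0.68
SYN074	S_pombe	PKTQNNINSYFKKDE	4	11	unknown	C	NA	NA	NA	D	0.93
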