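term	cui	semtypes
diabetes	C0011849	dsyn
type 2 diabetes	C0011860	dsyn
type 0 diabetes	C0011860	dsyn
heart	C0018787	bpoc
heart disease	C0018799	dsyn
congenital heart disease	C0152021	dsyn
asthma	C0004096	dsyn
high blood pressure	C0020538	dsyn
hypertension	C0020538	dsyn
breast cancer	C0006142	neop
colon cancer	C0007102	neop
skin cancer	C0007114	neop
pelvic cancer	C0153583	neop
liver cancer	C0345904	neop
stroke	C0038454	dsyn
strokes	C0038454	dsyn
depression	C0011570	mobd
schizophrenia	C0036341	mobd
coronary artery disease	C0010054	dsyn
myocardial infarction	C0027051	dsyn
cystic fibrosis	C0010674	dsyn
hydrocephalus	C0020255	dsyn
unspecified background retinopathy	C0004608	dsyn
retinopathy	C0035309	dsyn
smoking	C0037369	inbe
alcohol abuse	C0085762	mobd
suicide	C0038661	inbe
mother	C0026591	famg
father	C0015671	famg
aunt	C0337576	famg
uncle	C0337577	famg
cousin	C0337580	famg
teacher	C0221457	prog
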