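aapp
acab
aggp
anab
bacs
bdsu
bdsy
bird
blor
bpoc
bsoj
cell
cgab
clna
cnce
comd
drdd
dsyn
elii
emod
euka
famg
fndg
fngs
ftcn
genf
gngm
hlca
hops
idcn
inbe
inch
inpo
inpr
irda
lang
mamm
menp
mnob
mobd
neop
npop
orch
orga
orgf
patf
phsf
phsu
plnt
podg
popg
qlco
qnco
sosy
spco
tisu
tmco
topp
virs
vita
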