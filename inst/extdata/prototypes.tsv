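# enzyme<TAB>prototype (first-described enzyme of the isoschizomer family)
AatII	AatII
AflII	AflII
AgeI	AgeI
AlwNI	AlwNI
ApaI	ApaI
AvrII	AvrII
BamHI	BamHI
BglII	BglII
BstXI	BstXI
ClaI	ClaI
DdeI	DdeI
DraI	DraI
DraIII	DraIII
EcoRI	EcoRI
EcoRV	EcoRV
HaeIII	HaeIII
HindIII	HindIII
HinfI	HinfI
HpaI	HpaI
KpnI	KpnI
MfeI	MfeI
MluI	MluI
MspI	HpaII
NcoI	NcoI
NdeI	NdeI
NheI	NheI
NotI	NotI
NsiI	NsiI
PstI	PstI
PvuI	PvuI
PvuII	PvuII
SacI	SacI
SalI	SalI
ScaI	ScaI
SmaI	SmaI
SpeI	SpeI
SphI	SphI
StuI	StuI
XbaI	XbaI
XcmI	XcmI
XhoI	XhoI
XmaI	SmaI
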