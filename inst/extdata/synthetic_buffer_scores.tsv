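# enzyme<TAB>buffer<TAB>raw activity (synthetic, 0-100 scale)
AatII	standard	34
AatII	thermopol	63
AatII	phusion	87
AatII	crimson	95
AflII	standard	77
AflII	thermopol	95
AflII	phusion	49
AflII	crimson	100
AgeI	standard	21
AgeI	thermopol	0
AgeI	phusion	2
AgeI	crimson	6
AlwNI	standard	92
AlwNI	thermopol	71
AlwNI	phusion	8
AlwNI	crimson	74
ApaI	standard	29
ApaI	thermopol	34
ApaI	phusion	64
ApaI	crimson	3
AvrII	standard	46
AvrII	thermopol	71
AvrII	phusion	3
AvrII	crimson	69
BamHI	standard	0
BamHI	thermopol	89
BamHI	phusion	45
BamHI	crimson	63
BglII	standard	14
BglII	thermopol	14
BglII	phusion	97
BglII	crimson	43
BstXI	standard	94
BstXI	thermopol	49
BstXI	phusion	22
BstXI	crimson	3
ClaI	standard	54
ClaI	thermopol	100
ClaI	phusion	42
ClaI	crimson	5
DdeI	standard	61
DdeI	thermopol	1
DdeI	phusion	53
DdeI	crimson	70
DraI	standard	42
DraI	thermopol	30
DraI	phusion	9
DraI	crimson	40
DraIII	standard	29
DraIII	thermopol	30
DraIII	phusion	81
DraIII	crimson	68
EcoRI	standard	22
EcoRI	thermopol	17
EcoRI	phusion	68
EcoRI	crimson	61
EcoRV	standard	86
EcoRV	thermopol	24
EcoRV	phusion	12
EcoRV	crimson	84
HaeIII	standard	95
HaeIII	thermopol	69
HaeIII	phusion	89
HaeIII	crimson	64
HindIII	standard	51
HindIII	thermopol	31
HindIII	phusion	100
HindIII	crimson	8
HinfI	standard	54
HinfI	thermopol	4
HinfI	phusion	98
HinfI	crimson	57
HpaI	standard	83
HpaI	thermopol	8
HpaI	phusion	5
HpaI	crimson	93
KpnI	standard	65
KpnI	thermopol	29
KpnI	phusion	54
KpnI	crimson	78
MfeI	standard	9
MfeI	thermopol	13
MfeI	phusion	20
MfeI	crimson	74
MluI	standard	38
MluI	thermopol	77
MluI	phusion	55
MluI	crimson	51
MspI	standard	48
MspI	thermopol	54
MspI	phusion	17
MspI	crimson	47
NcoI	standard	100
NcoI	thermopol	13
NcoI	phusion	93
NcoI	crimson	79
NdeI	standard	63
NdeI	thermopol	96
NdeI	phusion	44
NdeI	crimson	30
NheI	standard	20
NheI	thermopol	89
NheI	phusion	37
NheI	crimson	13
NotI	standard	40
NotI	thermopol	58
NotI	phusion	82
NotI	crimson	45
NsiI	standard	26
NsiI	thermopol	45
NsiI	phusion	53
NsiI	crimson	82
PstI	standard	41
PstI	thermopol	18
PstI	phusion	49
PstI	crimson	3
PvuI	standard	48
PvuI	thermopol	77
PvuI	phusion	54
PvuI	crimson	22
PvuII	standard	12
PvuII	thermopol	71
PvuII	phusion	17
PvuII	crimson	57
SacI	standard	10
SacI	thermopol	73
SacI	phusion	12
SacI	crimson	80
SalI	standard	46
SalI	thermopol	84
SalI	phusion	83
SalI	crimson	89
ScaI	standard	37
ScaI	thermopol	82
ScaI	phusion	21
ScaI	crimson	46
SmaI	standard	30
SmaI	thermopol	37
SmaI	phusion	73
SmaI	crimson	68
SpeI	standard	3
SpeI	thermopol	50
SpeI	phusion	90
SpeI	crimson	72
SphI	standard	42
SphI	thermopol	25
SphI	phusion	45
SphI	crimson	74
StuI	standard	14
StuI	thermopol	2
StuI	phusion	15
StuI	crimson	9
XbaI	standard	11
XbaI	thermopol	33
XbaI	phusion	8
XbaI	crimson	38
XcmI	standard	36
XcmI	thermopol	47
XcmI	phusion	16
XcmI	crimson	48
XhoI	standard	51
XhoI	thermopol	39
XhoI	phusion	42
XhoI	crimson	37
XmaI	standard	99
XmaI	thermopol	43
XmaI	phusion	12
XmaI	crimson	10
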