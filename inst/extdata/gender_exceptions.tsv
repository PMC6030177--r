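token	gender	number
base	f	singular
bases	f	plural
ápice	m	singular
ápices	m	plural
margen	m	singular
márgenes	m	plural
tallo	m	singular
envés	m	singular
haz	m	singular
vez	f	singular
veces	f	plural
flor	f	singular
flores	f	plural
cáliz	m	singular
nuez	f	singular
nueces	f	plural
superficie	f	singular
lámina	f	singular
corteza	f	singular
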