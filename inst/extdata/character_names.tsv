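state_en	character
acuminate	shape
acute	shape
alternate	arrangement
black	colouration
brown	colouration
caudate	shape
compound	architecture
cordate	shape
coriaceous	texture
cream	colouration
deciduous	duration
dentate	shape
double	architecture
elliptic	arrangement
elliptic	shape
entire	shape
erect	orientation
fasciculate	arrangement
glabrous	pubescence
grayish	colouration
green	colouration
greenish	colouration
heart-shaped	shape
lanceolate	shape
membranaceous	texture
mucronate	shape
oblong	shape
obovate	shape
obtuse	shape
opposite	arrangement
orange	colouration
ovate	shape
pale	colouration
pendulous	orientation
persistent	duration
pilose	pubescence
pubescent	pubescence
red	colouration
reddish	colouration
revolute	shape
rounded	shape
rugose	relief
scattered	arrangement
serrate	shape
serrated	shape
simple	architecture
smooth	relief
spaced	arrangement
subcordate	shape
subentire	shape
tomentose	pubescence
tomentulose	pubescence
truncate	shape
white	colouration
yellow	colouration
yellowish	colouration
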