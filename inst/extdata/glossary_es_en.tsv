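es	en
hoja	leaf
flor	flower
fruto	fruit
semilla	seed
tallo	stem
rama	branch
ramita	twig
ápice	apex
base	base
margen	margin
lámina	blade
pecíolo	petiole
corteza	bark
tricoma	trichome
arilo	aril
racimo	raceme
vena	vein
nervadura	nervation
estípula	stipule
bráctea	bract
cáliz	calyx
corola	corolla
estambre	stamen
petalo	petal
sepalo	sepal
ovario	ovary
inflorescencia	inflorescence
panícula	panicle
espiga	spike
yema	bud
espina	spine
lenticela	lenticel
superficie	surface
nuez	nut
árbol	tree
arbusto	shrub
puntuación	dot
grupo	group
parte	part
planta	plant
estría	stria
pelo	hair
altura	height
ancho	width
longitud	length
diámetro	diameter
grosor	thickness
hojas	leaves
flores	flowers
frutos	fruits
semillas	seeds
tallos	stems
ramas	branches
ramitas	twigs
bases	bases
márgenes	margins
láminas	blades
pecíolos	petioles
tricomas	trichomes
arilos	arils
racimos	racemes
venas	veins
nervaduras	nervations
estípulas	stipules
brácteas	bracts
corolas	corollas
estambres	stamens
petalos	petals
sepalos	sepals
ovarios	ovaries
inflorescencias	inflorescences
panículas	panicles
espigas	spikes
yemas	buds
espinas	spines
lenticelas	lenticels
superficies	surfaces
nueces	nuts
árboles	trees
arbustos	shrubs
puntuaciones	dots
grupos	groups
partes	parts
plantas	plants
estrías	striae
pelos	hairs
envés	underside
haz	upperside
simple	simple
simples	simple
doble	double
dobles	double
compuesto	compound
compuesta	compound
compuestos	compound
compuestas	compound
alterno	alternate
alterna	alternate
alternos	alternate
alternas	alternate
opuesto	opposite
opuesta	opposite
opuestos	opposite
opuestas	opposite
fasciculado	fasciculate
fasciculada	fasciculate
fasciculados	fasciculate
fasciculadas	fasciculate
disperso	scattered
dispersa	scattered
dispersos	scattered
dispersas	scattered
espaciado	spaced
espaciada	spaced
espaciados	spaced
espaciadas	spaced
elíptico	elliptic
elíptica	elliptic
elípticos	elliptic
elípticas	elliptic
oblongo	oblong
oblonga	oblong
oblongos	oblong
oblongas	oblong
ovado	ovate
ovada	ovate
ovados	ovate
ovadas	ovate
obovado	obovate
obovada	obovate
obovados	obovate
obovadas	obovate
lanceolado	lanceolate
lanceolada	lanceolate
lanceolados	lanceolate
lanceoladas	lanceolate
acuminado	acuminate
acuminada	acuminate
acuminados	acuminate
acuminadas	acuminate
caudado	caudate
caudada	caudate
caudados	caudate
caudadas	caudate
agudo	acute
aguda	acute
agudos	acute
agudas	acute
obtuso	obtuse
obtusa	obtuse
obtusos	obtuse
obtusas	obtuse
redondeado	rounded
redondeada	rounded
redondeados	rounded
redondeadas	rounded
cordado	cordate
cordada	cordate
cordados	cordate
cordadas	cordate
subcordado	subcordate
subcordada	subcordate
subcordados	subcordate
subcordadas	subcordate
truncado	truncate
truncada	truncate
truncados	truncate
truncadas	truncate
aserrado	serrate
aserrada	serrate
aserrados	serrate
aserradas	serrate
serrado	serrated
serrada	serrated
serrados	serrated
serradas	serrated
dentado	dentate
dentada	dentate
dentados	dentate
dentadas	dentate
mucronado	mucronate
mucronada	mucronate
mucronados	mucronate
mucronadas	mucronate
entero	entire
entera	entire
enteros	entire
enteras	entire
subentero	subentire
subentera	subentire
subenteros	subentire
subenteras	subentire
revoluto	revolute
revoluta	revolute
revolutos	revolute
revolutas	revolute
acorazonado	heart-shaped
acorazonada	heart-shaped
acorazonados	heart-shaped
acorazonadas	heart-shaped
blanco	white
blanca	white
blancos	white
blancas	white
rojo	red
roja	red
rojos	red
rojas	red
amarillo	yellow
amarilla	yellow
amarillos	yellow
amarillas	yellow
anaranjado	orange
anaranjada	orange
anaranjados	orange
anaranjadas	orange
verde	green
verdes	green
verdoso	greenish
verdosa	greenish
verdosos	greenish
verdosas	greenish
amarillento	yellowish
amarillenta	yellowish
amarillentos	yellowish
amarillentas	yellowish
rojizo	reddish
rojiza	reddish
rojizos	reddish
rojizas	reddish
pálido	pale
pálida	pale
pálidos	pale
pálidas	pale
negro	black
negra	black
negros	black
negras	black
grisáceo	grayish
grisácea	grayish
grisáceos	grayish
grisáceas	grayish
pardo	brown
parda	brown
pardos	brown
pardas	brown
crema	cream
glabro	glabrous
glabra	glabrous
glabros	glabrous
glabras	glabrous
pubescente	pubescent
pubescentes	pubescent
tomentoso	tomentose
tomentosa	tomentose
tomentosos	tomentose
tomentosas	tomentose
tomentuloso	tomentulose
tomentulosa	tomentulose
tomentulosos	tomentulose
tomentulosas	tomentulose
piloso	pilose
pilosa	pilose
pilosos	pilose
pilosas	pilose
deciduo	deciduous
decidua	deciduous
deciduos	deciduous
deciduas	deciduous
persistente	persistent
persistentes	persistent
erecto	erect
erecta	erect
erectos	erect
erectas	erect
péndulo	pendulous
péndula	pendulous
péndulos	pendulous
péndulas	pendulous
coriáceo	coriaceous
coriácea	coriaceous
coriáceos	coriaceous
coriáceas	coriaceous
membranáceo	membranaceous
membranácea	membranaceous
membranáceos	membranaceous
membranáceas	membranaceous
liso	smooth
lisa	smooth
lisos	smooth
lisas	smooth
rugoso	rugose
rugosa	rugose
rugosos	rugose
rugosas	rugose
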