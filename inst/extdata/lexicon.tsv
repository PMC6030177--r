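token	tag	gender	number
de	S	unknown	unknown
en	S	unknown	unknown
por	S	unknown	unknown
sobre	S	unknown	unknown
entre	S	unknown	unknown
desde	S	unknown	unknown
hasta	S	unknown	unknown
hacia	S	unknown	unknown
a	S	unknown	unknown
con	S	unknown	unknown
sin	S	unknown	unknown
durante	S	unknown	unknown
o	C	unknown	unknown
u	C	unknown	unknown
y	C	unknown	unknown
e	C	unknown	unknown
ni	C	unknown	unknown
el	D	unknown	unknown
la	D	unknown	unknown
los	D	unknown	unknown
las	D	unknown	unknown
un	D	unknown	unknown
una	D	unknown	unknown
unos	D	unknown	unknown
unas	D	unknown	unknown
lo	D	unknown	unknown
varios	D	unknown	unknown
varias	D	unknown	unknown
algunos	D	unknown	unknown
algunas	D	unknown	unknown
numerosos	D	unknown	unknown
numerosas	D	unknown	unknown
pocos	D	unknown	unknown
pocas	D	unknown	unknown
muchos	D	unknown	unknown
muchas	D	unknown	unknown
todos	D	unknown	unknown
todas	D	unknown	unknown
levemente	R	unknown	unknown
finamente	R	unknown	unknown
densamente	R	unknown	unknown
ligeramente	R	unknown	unknown
usualmente	R	unknown	unknown
raramente	R	unknown	unknown
esparcidamente	R	unknown	unknown
cortamente	R	unknown	unknown
muy	R	unknown	unknown
algo	R	unknown	unknown
casi	R	unknown	unknown
veces	R	unknown	unknown
generalmente	R	unknown	unknown
frecuentemente	R	unknown	unknown
comúnmente	R	unknown	unknown
marcadamente	R	unknown	unknown
escasamente	R	unknown	unknown
diminutamente	R	unknown	unknown
apenas	R	unknown	unknown
espaciadamente	R	unknown	unknown
largo	R	unknown	unknown
m	U	unknown	unknown
cm	U	unknown	unknown
mm	U	unknown	unknown
dm	U	unknown	unknown
km	U	unknown	unknown
salen	V	unknown	unknown
nacen	V	unknown	unknown
crecen	V	unknown	unknown
forman	V	unknown	unknown
presentan	V	unknown	unknown
tornan	V	unknown	unknown
vuelven	V	unknown	unknown
miden	V	unknown	unknown
hoja	E	f	singular
flor	E	f	singular
fruto	E	m	singular
semilla	E	f	singular
tallo	E	m	singular
rama	E	f	singular
ramita	E	f	singular
ápice	E	m	singular
base	E	f	singular
margen	E	m	singular
lámina	E	f	singular
pecíolo	E	m	singular
corteza	E	f	singular
tricoma	E	m	singular
arilo	E	m	singular
racimo	E	m	singular
vena	E	f	singular
nervadura	E	f	singular
estípula	E	f	singular
bráctea	E	f	singular
cáliz	E	m	singular
corola	E	f	singular
estambre	E	m	singular
petalo	E	m	singular
sepalo	E	m	singular
ovario	E	m	singular
inflorescencia	E	f	singular
panícula	E	f	singular
espiga	E	f	singular
yema	E	f	singular
espina	E	f	singular
lenticela	E	f	singular
superficie	E	f	singular
nuez	E	f	singular
árbol	E	m	singular
arbusto	E	m	singular
puntuación	E	f	singular
grupo	E	m	singular
parte	E	f	singular
planta	E	f	singular
estría	E	f	singular
pelo	E	m	singular
altura	E	f	singular
ancho	E	m	singular
longitud	E	f	singular
diámetro	E	m	singular
grosor	E	m	singular
hojas	E	f	plural
flores	E	f	plural
frutos	E	m	plural
semillas	E	f	plural
tallos	E	m	plural
ramas	E	f	plural
ramitas	E	f	plural
bases	E	f	plural
márgenes	E	m	plural
láminas	E	f	plural
pecíolos	E	m	plural
tricomas	E	m	plural
arilos	E	m	plural
racimos	E	m	plural
venas	E	f	plural
nervaduras	E	f	plural
estípulas	E	f	plural
brácteas	E	f	plural
corolas	E	f	plural
estambres	E	m	plural
petalos	E	m	plural
sepalos	E	m	plural
ovarios	E	m	plural
inflorescencias	E	f	plural
panículas	E	f	plural
espigas	E	f	plural
yemas	E	f	plural
espinas	E	f	plural
lenticelas	E	f	plural
superficies	E	f	plural
nueces	E	f	plural
árboles	E	m	plural
arbustos	E	m	plural
puntuaciones	E	f	plural
grupos	E	m	plural
partes	E	f	plural
plantas	E	f	plural
estrías	E	f	plural
pelos	E	m	plural
envés	E	m	singular
haz	E	m	singular
simple	A	unknown	singular
simples	A	unknown	plural
doble	A	unknown	singular
dobles	A	unknown	plural
compuesto	A	m	singular
compuesta	A	f	singular
compuestos	A	m	plural
compuestas	A	f	plural
alterno	A	m	singular
alterna	A	f	singular
alternos	A	m	plural
alternas	A	f	plural
opuesto	A	m	singular
opuesta	A	f	singular
opuestos	A	m	plural
opuestas	A	f	plural
fasciculado	A	m	singular
fasciculada	A	f	singular
fasciculados	A	m	plural
fasciculadas	A	f	plural
disperso	A	m	singular
dispersa	A	f	singular
dispersos	A	m	plural
dispersas	A	f	plural
espaciado	A	m	singular
espaciada	A	f	singular
espaciados	A	m	plural
espaciadas	A	f	plural
elíptico	A	m	singular
elíptica	A	f	singular
elípticos	A	m	plural
elípticas	A	f	plural
oblongo	A	m	singular
oblonga	A	f	singular
oblongos	A	m	plural
oblongas	A	f	plural
ovado	A	m	singular
ovada	A	f	singular
ovados	A	m	plural
ovadas	A	f	plural
obovado	A	m	singular
obovada	A	f	singular
obovados	A	m	plural
obovadas	A	f	plural
lanceolado	A	m	singular
lanceolada	A	f	singular
lanceolados	A	m	plural
lanceoladas	A	f	plural
acuminado	A	m	singular
acuminada	A	f	singular
acuminados	A	m	plural
acuminadas	A	f	plural
caudado	A	m	singular
caudada	A	f	singular
caudados	A	m	plural
caudadas	A	f	plural
agudo	A	m	singular
aguda	A	f	singular
agudos	A	m	plural
agudas	A	f	plural
obtuso	A	m	singular
obtusa	A	f	singular
obtusos	A	m	plural
obtusas	A	f	plural
redondeado	A	m	singular
redondeada	A	f	singular
redondeados	A	m	plural
redondeadas	A	f	plural
cordado	A	m	singular
cordada	A	f	singular
cordados	A	m	plural
cordadas	A	f	plural
subcordado	A	m	singular
subcordada	A	f	singular
subcordados	A	m	plural
subcordadas	A	f	plural
truncado	A	m	singular
truncada	A	f	singular
truncados	A	m	plural
truncadas	A	f	plural
aserrado	A	m	singular
aserrada	A	f	singular
aserrados	A	m	plural
aserradas	A	f	plural
serrado	A	m	singular
serrada	A	f	singular
serrados	A	m	plural
serradas	A	f	plural
dentado	A	m	singular
dentada	A	f	singular
dentados	A	m	plural
dentadas	A	f	plural
mucronado	A	m	singular
mucronada	A	f	singular
mucronados	A	m	plural
mucronadas	A	f	plural
entero	A	m	singular
entera	A	f	singular
enteros	A	m	plural
enteras	A	f	plural
subentero	A	m	singular
subentera	A	f	singular
subenteros	A	m	plural
subenteras	A	f	plural
revoluto	A	m	singular
revoluta	A	f	singular
revolutos	A	m	plural
revolutas	A	f	plural
acorazonado	A	m	singular
acorazonada	A	f	singular
acorazonados	A	m	plural
acorazonadas	A	f	plural
blanco	A	m	singular
blanca	A	f	singular
blancos	A	m	plural
blancas	A	f	plural
rojo	A	m	singular
roja	A	f	singular
rojos	A	m	plural
rojas	A	f	plural
amarillo	A	m	singular
amarilla	A	f	singular
amarillos	A	m	plural
amarillas	A	f	plural
anaranjado	A	m	singular
anaranjada	A	f	singular
anaranjados	A	m	plural
anaranjadas	A	f	plural
verde	A	unknown	singular
verdes	A	unknown	plural
verdoso	A	m	singular
verdosa	A	f	singular
verdosos	A	m	plural
verdosas	A	f	plural
amarillento	A	m	singular
amarillenta	A	f	singular
amarillentos	A	m	plural
amarillentas	A	f	plural
rojizo	A	m	singular
rojiza	A	f	singular
rojizos	A	m	plural
rojizas	A	f	plural
pálido	A	m	singular
pálida	A	f	singular
pálidos	A	m	plural
pálidas	A	f	plural
negro	A	m	singular
negra	A	f	singular
negros	A	m	plural
negras	A	f	plural
grisáceo	A	m	singular
grisácea	A	f	singular
grisáceos	A	m	plural
grisáceas	A	f	plural
pardo	A	m	singular
parda	A	f	singular
pardos	A	m	plural
pardas	A	f	plural
crema	A	unknown	unknown
glabro	A	m	singular
glabra	A	f	singular
glabros	A	m	plural
glabras	A	f	plural
pubescente	A	unknown	singular
pubescentes	A	unknown	plural
tomentoso	A	m	singular
tomentosa	A	f	singular
tomentosos	A	m	plural
tomentosas	A	f	plural
tomentuloso	A	m	singular
tomentulosa	A	f	singular
tomentulosos	A	m	plural
tomentulosas	A	f	plural
piloso	A	m	singular
pilosa	A	f	singular
pilosos	A	m	plural
pilosas	A	f	plural
deciduo	A	m	singular
decidua	A	f	singular
deciduos	A	m	plural
deciduas	A	f	plural
persistente	A	unknown	singular
persistentes	A	unknown	plural
erecto	A	m	singular
erecta	A	f	singular
erectos	A	m	plural
erectas	A	f	plural
péndulo	A	m	singular
péndula	A	f	singular
péndulos	A	m	plural
péndulas	A	f	plural
coriáceo	A	m	singular
coriácea	A	f	singular
coriáceos	A	m	plural
coriáceas	A	f	plural
membranáceo	A	m	singular
membranácea	A	f	singular
membranáceos	A	m	plural
membranáceas	A	f	plural
liso	A	m	singular
lisa	A	f	singular
lisos	A	m	plural
lisas	A	f	plural
rugoso	A	m	singular
rugosa	A	f	singular
rugosos	A	m	plural
rugosas	A	f	plural
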