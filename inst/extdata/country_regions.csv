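iso3,region
ALB,Europe
AND,Europe
AUT,Europe
BEL,Europe
BGR,Europe
BIH,Europe
BLR,Europe
CHE,Europe
CZE,Europe
DEU,Europe
DNK,Europe
ESP,Europe
EST,Europe
FIN,Europe
FRA,Europe
GBR,Europe
GRC,Europe
HRV,Europe
HUN,Europe
IRL,Europe
ISL,Europe
ITA,Europe
LIE,Europe
LTU,Europe
LUX,Europe
LVA,Europe
MCO,Europe
MDA,Europe
MKD,Europe
MLT,Europe
MNE,Europe
NLD,Europe
NOR,Europe
POL,Europe
PRT,Europe
ROU,Europe
RUS,Europe
SMR,Europe
SRB,Europe
SVK,Europe
SVN,Europe
SWE,Europe
UKR,Europe
BMU,Northern America
CAN,Northern America
GRL,Northern America
USA,Northern America
ARG,Latin America and Caribbean
BHS,Latin America and Caribbean
BLZ,Latin America and Caribbean
BOL,Latin America and Caribbean
BRA,Latin America and Caribbean
BRB,Latin America and Caribbean
CHL,Latin America and Caribbean
COL,Latin America and Caribbean
CRI,Latin America and Caribbean
CUB,Latin America and Caribbean
DOM,Latin America and Caribbean
ECU,Latin America and Caribbean
GTM,Latin America and Caribbean
GUY,Latin America and Caribbean
HND,Latin America and Caribbean
HTI,Latin America and Caribbean
JAM,Latin America and Caribbean
MEX,Latin America and Caribbean
NIC,Latin America and Caribbean
PAN,Latin America and Caribbean
PER,Latin America and Caribbean
PRY,Latin America and Caribbean
SLV,Latin America and Caribbean
SUR,Latin America and Caribbean
TTO,Latin America and Caribbean
URY,Latin America and Caribbean
VEN,Latin America and Caribbean
ARE,Northern Africa and Western Asia
ARM,Northern Africa and Western Asia
AZE,Northern Africa and Western Asia
BHR,Northern Africa and Western Asia
CYP,Northern Africa and Western Asia
DZA,Northern Africa and Western Asia
EGY,Northern Africa and Western Asia
GEO,Northern Africa and Western Asia
IRQ,Northern Africa and Western Asia
ISR,Northern Africa and Western Asia
JOR,Northern Africa and Western Asia
KWT,Northern Africa and Western Asia
LBN,Northern Africa and Western Asia
LBY,Northern Africa and Western Asia
MAR,Northern Africa and Western Asia
OMN,Northern Africa and Western Asia
PSE,Northern Africa and Western Asia
QAT,Northern Africa and Western Asia
SAU,Northern Africa and Western Asia
SDN,Northern Africa and Western Asia
SYR,Northern Africa and Western Asia
TUN,Northern Africa and Western Asia
TUR,Northern Africa and Western Asia
YEM,Northern Africa and Western Asia
AGO,Sub-Saharan Africa
BEN,Sub-Saharan Africa
BFA,Sub-Saharan Africa
BWA,Sub-Saharan Africa
CAF,Sub-Saharan Africa
CIV,Sub-Saharan Africa
CMR,Sub-Saharan Africa
COD,Sub-Saharan Africa
COG,Sub-Saharan Africa
ERI,Sub-Saharan Africa
ETH,Sub-Saharan Africa
GAB,Sub-Saharan Africa
GHA,Sub-Saharan Africa
GIN,Sub-Saharan Africa
GMB,Sub-Saharan Africa
KEN,Sub-Saharan Africa
LBR,Sub-Saharan Africa
LSO,Sub-Saharan Africa
MDG,Sub-Saharan Africa
MLI,Sub-Saharan Africa
MOZ,Sub-Saharan Africa
MRT,Sub-Saharan Africa
MWI,Sub-Saharan Africa
NAM,Sub-Saharan Africa
NER,Sub-Saharan Africa
NGA,Sub-Saharan Africa
RWA,Sub-Saharan Africa
SEN,Sub-Saharan Africa
SLE,Sub-Saharan Africa
SOM,Sub-Saharan Africa
SSD,Sub-Saharan Africa
TCD,Sub-Saharan Africa
TGO,Sub-Saharan Africa
TZA,Sub-Saharan Africa
UGA,Sub-Saharan Africa
ZAF,Sub-Saharan Africa
ZMB,Sub-Saharan Africa
ZWE,Sub-Saharan Africa
AFG,Central and Southern Asia
BGD,Central and Southern Asia
BTN,Central and Southern Asia
IND,Central and Southern Asia
IRN,Central and Southern Asia
KAZ,Central and Southern Asia
KGZ,Central and Southern Asia
LKA,Central and Southern Asia
MDV,Central and Southern Asia
NPL,Central and Southern Asia
PAK,Central and Southern Asia
TJK,Central and Southern Asia
TKM,Central and Southern Asia
UZB,Central and Southern Asia
BRN,Eastern and South-Eastern Asia
CHN,Eastern and South-Eastern Asia
HKG,Eastern and South-Eastern Asia
IDN,Eastern and South-Eastern Asia
JPN,Eastern and South-Eastern Asia
KHM,Eastern and South-Eastern Asia
KOR,Eastern and South-Eastern Asia
LAO,Eastern and South-Eastern Asia
MAC,Eastern and South-Eastern Asia
MMR,Eastern and South-Eastern Asia
MNG,Eastern and South-Eastern Asia
MYS,Eastern and South-Eastern Asia
PHL,Eastern and South-Eastern Asia
PRK,Eastern and South-Eastern Asia
SGP,Eastern and South-Eastern Asia
THA,Eastern and South-Eastern Asia
TLS,Eastern and South-Eastern Asia
TWN,Eastern and South-Eastern Asia
VNM,Eastern and South-Eastern Asia
AUS,Oceania
FJI,Oceania
KIR,Oceania
NZL,Oceania
PNG,Oceania
SLB,Oceania
TON,Oceania
VUT,Oceania
WSM,Oceania
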