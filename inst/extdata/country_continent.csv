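country,continent
CN,Asia
CHINA,Asia
JP,Asia
JAPAN,Asia
KR,Asia
KOREA (THE REPUBLIC OF),Asia
IN,Asia
INDIA,Asia
TR,Asia
TURKEY,Asia
IR,Asia
IRAN,Asia
SA,Asia
SAUDI ARABIA,Asia
TH,Asia
THAILAND,Asia
VN,Asia
VIET NAM,Asia
ID,Asia
INDONESIA,Asia
IL,Asia
ISRAEL,Asia
US,Americas
UNITED STATES,Americas
COUNTRY NOT SPECIFIED,unknown
CA,Americas
CANADA,Americas
BR,Americas
BRAZIL,Americas
MX,Americas
MEXICO,Americas
AR,Americas
ARGENTINA,Americas
CO,Americas
COLOMBIA,Americas
CL,Americas
CHILE,Americas
PE,Americas
PERU,Americas
GB,Europe
UNITED KINGDOM,Europe
DE,Europe
GERMANY,Europe
FR,Europe
FRANCE,Europe
IT,Europe
ITALY,Europe
ES,Europe
SPAIN,Europe
NL,Europe
NETHERLANDS,Europe
PL,Europe
POLAND,Europe
SE,Europe
SWEDEN,Europe
CH,Europe
SWITZERLAND,Europe
GR,Europe
GREECE,Europe
PT,Europe
PORTUGAL,Europe
BE,Europe
BELGIUM,Europe
AT,Europe
AUSTRIA,Europe
DK,Europe
DENMARK,Europe
NO,Europe
NORWAY,Europe
FI,Europe
FINLAND,Europe
IE,Europe
IRELAND,Europe
RU,Europe
RUSSIAN FEDERATION,Europe
UA,Europe
UKRAINE,Europe
EG,Africa
EGYPT,Africa
ZA,Africa
SOUTH AFRICA,Africa
NG,Africa
NIGERIA,Africa
KE,Africa
KENYA,Africa
MA,Africa
MOROCCO,Africa
TN,Africa
TUNISIA,Africa
DZ,Africa
ALGERIA,Africa
ET,Africa
ETHIOPIA,Africa
GH,Africa
GHANA,Africa
AU,Oceania
AUSTRALIA,Oceania
NZ,Oceania
NEW ZEALAND,Oceania
FJ,Oceania
FIJI,Oceania
PG,Oceania
PAPUA NEW GUINEA,Oceania
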