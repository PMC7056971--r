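strain	allele	previously_reported	reference
C57BL/6J	Ahr_b1	yes	yes
C57BL/6NJ	Ahr_b1	yes	no
C57L/J	Ahr_b1	yes	no
C57BL/10J	Ahr_b1	yes	no
C57BR/cdJ	Ahr_b1	yes	no
C58/J	Ahr_b1	yes	no
A/J	Ahr_b2	yes	no
BALB/cJ	Ahr_b2	yes	no
BTBR T+ Itpr3tf/J	Ahr_b2	no	no
BUB/BnJ	Ahr_b2	yes	no
C3H/HeJ	Ahr_b2	yes	no
C3H/HeH	Ahr_b2	yes	no
CBA/J	Ahr_b2	yes	no
FVB/NJ	Ahr_b2	no	no
SEA/GnJ	Ahr_b2	yes	no
WSB/EiJ	Ahr_b2	no	no
LEWES/EiJ	Ahr_b2	no	no
SPRET/EiJ	Ahr_b3	yes	no
MOLF/EiJ	Ahr_b3	yes	no
PWK/PhJ	Ahr_b3	no	no
129S1/SvImJ	Ahr_d	yes	no
129S5SvEvBrD	Ahr_d	yes	no
129P2/OlaHsd	Ahr_d	yes	no
AKR/J	Ahr_d	yes	no
DBA1/J	Ahr_d	no	no
DBA2/J	Ahr_d	yes	no
I/LnJ	Ahr_d	yes	no
KK/HiJ	Ahr_d	no	no
LP/J	Ahr_d	yes	no
NOD/ShilLtJ	Ahr_d	no	no
NZB/B1NJ	Ahr_d	yes	no
NZO/HlltJ	Ahr_d	no	no
NZW/LacJ	Ahr_d	no	no
RF/J	Ahr_d	yes	no
ST/bJ	Ahr_d	yes	no
ZALENDE/EiJ	Ahr_d	no	no
CAST/EiJ	Ahr_d	yes	no
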