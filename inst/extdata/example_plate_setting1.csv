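Well,Target,Task,Cq,Quantity
A1,transgene,standard,20.4180718893410,100000
A2,transgene,standard,20.3415524969520,100000
A3,transgene,standard,20.5287220010934,100000
A4,transgene,standard,23.5249363686111,10000
A5,transgene,standard,23.9037928068568,10000
A6,transgene,standard,23.5318357524164,10000
A7,transgene,standard,27.0368852919565,1000
A8,transgene,standard,26.8732380779634,1000
A9,transgene,standard,26.9484632915907,1000
A10,transgene,standard,30.6119161546068,100
A11,transgene,standard,30.3648416780502,100
A12,transgene,standard,30.3939728933902,100
B1,transgene,standard,33.5981431940360,10
B2,transgene,standard,33.8813323011420,10
B3,transgene,standard,33.7789376255086,10
B4,transgene,ntc,undetermined,
B5,transgene,sample,32.5643644579299,
B6,transgene,sample,32.6820640466366,
B7,transgene,sample,32.2357534356408,
B8,transgene,sample,32.3494597853363,
B9,transgene,sample,32.2041062563357,
B10,transgene,sample,32.2782429337213,
B11,transgene,sample,32.3501220547878,
B12,transgene,sample,32.1972364449875,
C1,transgene,sample,32.7965456369989,
C2,transgene,sample,32.0941174452197,
C3,transgene,sample,33.0118238629740,
C4,transgene,sample,32.7706889031541,
C5,transgene,sample,32.0513158020056,
C6,transgene,sample,32.4274515635830,
C7,transgene,sample,31.7874193388661,
C8,transgene,sample,32.6955627698664,
C9,transgene,sample,32.2343577705249,
C10,transgene,sample,32.5541141487145,
C11,transgene,sample,32.1879174869770,
C12,transgene,sample,32.5407148211940,
D1,transgene,sample,32.2230768512445,
D2,transgene,sample,32.3393944385754,
D3,transgene,sample,32.3067444987137,
D4,transgene,sample,32.0323324981904,
D5,transgene,sample,32.8417495350525,
D6,transgene,sample,33.4325706235068,
D7,transgene,sample,32.4701505404386,
D8,transgene,sample,32.4476445947671,
D9,transgene,sample,32.4581061412800,
D10,transgene,sample,32.8051427557949,
D11,transgene,sample,31.4892917167195,
D12,transgene,sample,32.3403742422832,
E1,reference,standard,20.7722522806561,100000
E2,reference,standard,20.5420651490880,100000
E3,reference,standard,20.4544993522614,100000
E4,reference,standard,23.4583170013900,10000
E5,reference,standard,23.7353447817863,10000
E6,reference,standard,23.5520024890623,10000
E7,reference,standard,27.2176118642327,1000
E8,reference,standard,26.9932508860549,1000
E9,reference,standard,27.0114128820638,1000
E10,reference,standard,30.2883965404607,100
E11,reference,standard,30.1710683599567,100
E12,reference,standard,29.9548460905159,100
F1,reference,standard,33.5216150420016,10
F2,reference,standard,33.3776371984670,10
F3,reference,standard,33.6515333307136,10
F4,reference,ntc,undetermined,
F5,reference,sample,22.5902439190797,
F6,reference,sample,22.2864720426548,
F7,reference,sample,22.6391998061113,
F8,reference,sample,22.6344255707790,
F9,reference,sample,22.9275880363192,
F10,reference,sample,22.3556259905036,
F11,reference,sample,22.3879563530172,
F12,reference,sample,22.6150891783098,
G1,reference,sample,22.8695829808993,
G2,reference,sample,22.4032237206117,
G3,reference,sample,22.7778441249313,
G4,reference,sample,22.4917328161026,
G5,reference,sample,22.6043796766339,
G6,reference,sample,22.5875529204403,
G7,reference,sample,22.6281072403776,
G8,reference,sample,22.5980100894669,
G9,reference,sample,22.5242648244342,
G10,reference,sample,22.9407271996306,
G11,reference,sample,22.3581125064918,
G12,reference,sample,22.8189159297286,
H1,reference,sample,22.1934795201877,
H2,reference,sample,22.8372592019033,
H3,reference,sample,22.4686069559305,
H4,reference,sample,22.8379337536198,
H5,reference,sample,22.6926191381631,
H6,reference,sample,22.7640455373582,
H7,reference,sample,23.1238798814815,
H8,reference,sample,22.4340279519604,
H9,reference,sample,22.7242455069663,
H10,reference,sample,22.1334977382752,
H11,reference,sample,22.3246572600921,
H12,reference,sample,22.6011517969774,
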