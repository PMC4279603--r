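Well,Target,Task,Cq,Quantity
A1,transgene,standard,20.4610810124745,100000
A2,transgene,standard,20.4083414764753,100000
A3,transgene,standard,20.5653072953601,100000
A4,transgene,standard,23.4064751686925,10000
A5,transgene,standard,23.8519781119509,10000
A6,transgene,standard,23.5787954271932,10000
A7,transgene,standard,27.0289279056411,1000
A8,transgene,standard,27.0213690995774,1000
A9,transgene,standard,27.0234285835638,1000
A10,transgene,standard,30.5797440188730,100
A11,transgene,standard,30.3481396108694,100
A12,transgene,standard,30.4823298432104,100
B1,transgene,standard,33.6533950403564,10
B2,transgene,standard,33.8384680626951,10
B3,transgene,standard,33.7451980397253,10
B4,transgene,ntc,undetermined,
B5,transgene,sample,32.6995531295047,
B6,transgene,sample,32.7053943216900,
B7,transgene,sample,32.1757890467345,
B8,transgene,sample,32.2111442753821,
B9,transgene,sample,32.2388378144184,
B10,transgene,sample,32.2974200488348,
B11,transgene,sample,32.3375309268951,
B12,transgene,sample,32.0641538908301,
C1,transgene,sample,32.8572016173277,
C2,transgene,sample,32.0628676585261,
C3,transgene,sample,33.0452638128584,
C4,transgene,sample,32.7912049157250,
C5,transgene,sample,32.0277128486709,
C6,transgene,sample,32.4583110500025,
C7,transgene,sample,31.6760929708628,
C8,transgene,sample,32.8205833692077,
C9,transgene,sample,32.2561137013103,
C10,transgene,sample,32.4838200691190,
C11,transgene,sample,32.1595333709005,
C12,transgene,sample,32.4703330406978,
D1,transgene,sample,32.2299578511874,
D2,transgene,sample,32.3230428985791,
D3,transgene,sample,32.3449399201909,
D4,transgene,sample,32.0126660091446,
D5,transgene,sample,32.8579157556250,
D6,transgene,sample,33.2334822342926,
D7,transgene,sample,32.3904316147283,
D8,transgene,sample,32.5316364052173,
D9,transgene,sample,32.3978590276284,
D10,transgene,sample,32.7884196006332,
D11,transgene,sample,31.4835127842331,
D12,transgene,sample,32.4200227724990,
E1,reference,standard,20.8129243716554,100000
E2,reference,standard,20.5322192820341,100000
E3,reference,standard,20.4149046220915,100000
E4,reference,standard,23.5159133578913,10000
E5,reference,standard,23.7692108699267,10000
E6,reference,standard,23.3911695335263,10000
E7,reference,standard,27.2889807719745,1000
E8,reference,standard,26.9885602587867,1000
E9,reference,standard,26.8927013578093,1000
E10,reference,standard,30.3315656059479,100
E11,reference,standard,30.1815199175867,100
E12,reference,standard,29.9456210395426,100
F1,reference,standard,33.5725262116747,10
F2,reference,standard,33.4117700913982,10
F3,reference,standard,33.7090553270063,10
F4,reference,ntc,undetermined,
F5,reference,sample,22.5327638182265,
F6,reference,sample,22.3893011899184,
F7,reference,sample,22.5828913249743,
F8,reference,sample,22.5367748178286,
F9,reference,sample,22.9368959966085,
F10,reference,sample,22.4070984716450,
F11,reference,sample,22.3562385333979,
F12,reference,sample,22.5486429801803,
G1,reference,sample,22.8751998134270,
G2,reference,sample,22.4041343072037,
G3,reference,sample,22.7231277780764,
G4,reference,sample,22.3457924132875,
G5,reference,sample,22.6230309086498,
G6,reference,sample,22.6450369276616,
G7,reference,sample,22.6284491447108,
G8,reference,sample,22.5863479420314,
G9,reference,sample,22.5346289033602,
G10,reference,sample,22.8785229445662,
G11,reference,sample,22.3517633305730,
G12,reference,sample,22.7850531807394,
H1,reference,sample,22.1043274961526,
H2,reference,sample,22.8438033081343,
H3,reference,sample,22.4957848711665,
H4,reference,sample,22.7787495402526,
H5,reference,sample,22.7066156049534,
H6,reference,sample,22.6945553005583,
H7,reference,sample,23.0777259104818,
H8,reference,sample,22.4401262270363,
H9,reference,sample,22.6557521220664,
H10,reference,sample,22.1935590328852,
H11,reference,sample,22.2509138590577,
H12,reference,sample,22.5926006043805,
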