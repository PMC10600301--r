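lead_name,x,y
Fp1,-0.5004,0.85
Fpz,0,0.85
Fp2,0.5004,0.85
AF7,-0.6966,0.68
AF3,-0.3483,0.68
AFz,0,0.68
AF4,0.3483,0.68
AF8,0.6966,0.68
F7,-0.8227,0.5
F5,-0.617,0.5
F3,-0.4114,0.5
F1,-0.2057,0.5
Fz,0,0.5
F2,0.2057,0.5
F4,0.4114,0.5
F6,0.617,0.5
F8,0.8227,0.5
FT7,-0.9198,0.25
FC5,-0.6899,0.25
FC3,-0.4599,0.25
FC1,-0.23,0.25
FCz,0,0.25
FC2,0.23,0.25
FC4,0.4599,0.25
FC6,0.6899,0.25
FT8,0.9198,0.25
T7,-0.95,0
C5,-0.7125,0
C3,-0.475,0
C1,-0.2375,0
Cz,0,0
C2,0.2375,0
C4,0.475,0
C6,0.7125,0
T8,0.95,0
TP9,-0.9198,-0.25
TP7,-0.7359,-0.25
CP5,-0.5519,-0.25
CP3,-0.3679,-0.25
CP1,-0.184,-0.25
CPz,0,-0.25
CP2,0.184,-0.25
CP4,0.3679,-0.25
CP6,0.5519,-0.25
TP8,0.7359,-0.25
TP10,0.9198,-0.25
P7,-0.8227,-0.5
P5,-0.617,-0.5
P3,-0.4114,-0.5
P1,-0.2057,-0.5
Pz,0,-0.5
P2,0.2057,-0.5
P4,0.4114,-0.5
P6,0.617,-0.5
P8,0.8227,-0.5
PO7,-0.6966,-0.68
PO3,-0.3483,-0.68
POz,0,-0.68
PO4,0.3483,-0.68
PO8,0.6966,-0.68
O1,-0.5004,-0.85
Oz,0,-0.85
O2,0.5004,-0.85
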