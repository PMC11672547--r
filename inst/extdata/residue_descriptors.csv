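residue,hydropathy,residue_mass,charge_ph7.4,aromatic,aliphatic,polar,positive,negative,proline
A,1.8,71.0788,0,0,1,0,0,0,0
C,2.5,103.1388,0,0,0,1,0,0,0
D,-3.5,115.0886,-1,0,0,0,0,1,0
E,-3.5,129.1155,-1,0,0,0,0,1,0
F,2.8,147.1766,0,1,0,0,0,0,0
G,-0.4,57.0519,0,0,0,0,0,0,0
H,-3.2,137.1411,0,0,0,1,0,0,0
I,4.5,113.1594,0,0,1,0,0,0,0
K,-3.9,128.1741,1,0,0,0,1,0,0
L,3.8,113.1594,0,0,1,0,0,0,0
M,1.9,131.1926,0,0,0,0,0,0,0
N,-3.5,114.1038,0,0,0,1,0,0,0
P,-1.6,97.1167,0,0,0,0,0,0,1
Q,-3.5,128.1307,0,0,0,1,0,0,0
R,-4.5,156.1875,1,0,0,0,1,0,0
S,-0.8,87.0782,0,0,0,1,0,0,0
T,-0.7,101.1051,0,0,0,1,0,0,0
V,4.2,99.1326,0,0,1,0,0,0,0
W,-0.9,186.2132,0,1,0,0,0,0,0
Y,-1.3,163.176,0,1,0,1,0,0,0
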