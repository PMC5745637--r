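amino_acid,hydropathy_kyte_doolittle,hydrophilicity_hopp_woods,volume_zamyatnin,mass_residue,bulkiness_zimmerman,polarity_grantham,isoelectric_zimmerman,net_charge,flexibility_bhaskaran,helix_chou_fasman,sheet_chou_fasman
A,1.8,-0.5,88.6,71.08,11.5,8.1,6,0,0.357,1.42,0.83
C,2.5,-1,108.5,103.14,13.46,5.5,5.05,0,0.346,0.7,1.19
D,-3.5,3,111.1,115.09,11.68,13,2.77,-1,0.511,1.01,0.54
E,-3.5,3,138.4,129.12,13.57,12.3,3.22,-1,0.497,1.51,0.37
F,2.8,-2.5,189.9,147.18,19.8,5.2,5.48,0,0.314,1.13,1.38
G,-0.4,0,60.1,57.05,3.4,9,5.97,0,0.544,0.57,0.75
H,-3.2,-0.5,153.2,137.14,13.69,10.4,7.59,0.5,0.323,1,0.87
I,4.5,-1.8,166.7,113.16,21.4,5.2,6.02,0,0.462,1.08,1.6
K,-3.9,3,168.6,128.17,15.71,11.3,9.74,1,0.466,1.16,0.74
L,3.8,-1.8,166.7,113.16,21.4,4.9,5.98,0,0.365,1.21,1.3
M,1.9,-1.3,162.9,131.19,16.25,5.7,5.74,0,0.295,1.45,1.05
N,-3.5,0.2,114.1,114.1,12.82,11.6,5.41,0,0.463,0.67,0.89
P,-1.6,0,112.7,97.12,17.43,8,6.3,0,0.509,0.57,0.55
Q,-3.5,0.2,143.8,128.13,14.45,10.5,5.65,0,0.493,1.11,1.1
R,-4.5,3,173.4,156.19,14.28,10.5,10.76,1,0.529,0.98,0.93
S,-0.8,0.3,89,87.08,9.47,9.2,5.68,0,0.507,0.77,0.75
T,-0.7,-0.4,116.1,101.1,15.77,8.6,5.66,0,0.444,0.83,1.19
V,4.2,-1.5,140,99.13,21.57,5.9,5.96,0,0.386,1.06,1.7
W,-0.9,-3.4,227.8,186.21,21.67,5.4,5.89,0,0.305,1.08,1.37
Y,-1.3,-2.3,193.6,163.18,18.03,6.2,5.66,0,0.42,0.69,1.47
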