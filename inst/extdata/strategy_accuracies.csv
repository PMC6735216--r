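subject,group,sm1_4_channels,sm1_4,sm1_5_channels,sm1_5,erd_channels,erd
S1,proliferation,Cz C1 C3 C5,82.5,C1 C3 C5 FC3 CP3,82.5,CP1 Pz C1 TP8,92.5
S3,proliferation,Cz C1 C3 C5,67.5,C1 C3 C5 FC3 CP3,67.5,FC5 C4 C5 C1,80.0
S6,proliferation,Cz C1 C3 C5,60.0,C1 C3 C5 FC3 CP3,62.5,C4 CP2 AF8 C2,67.5
S9,proliferation,Cz C1 C3 C5,70.0,C1 C3 C5 FC3 CP3,72.5,C4 CP2 CP6 CP4,77.5
S5,SM1,Cz C1 C3 C5,67.5,C1 C3 C5 FC3 CP3,75.0,C3 CP1 FC3 C1,75.0
S7,SM1,Cz C1 C3 C5,72.5,C1 C3 C5 FC3 CP3,72.5,C1 C2 C3 C4,75.0
S10,SM1,Cz C2 C4 C6,65.0,C2 C4 C6 FC4 CP4,67.5,C4 AF3 F5 CP4,70.0
S12,SM1,Cz C1 C3 C5,65.0,C1 C3 C5 FC3 CP3,65.0,C3 FC3 C1 CP3,67.5
S8,others,Cz C1 C3 C5,85.0,C1 C3 C5 FC3 CP3,85.0,F7 FC2 C4 F5,87.5
S13,others,Cz C1 C3 C5,60.0,C1 C3 C5 FC3 CP3,62.5,Cz CP1 C1 C2,65.0
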