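# Two-slice dispersal multiplier matrices for the six Neotropical bioregions
# A North America, B Caribbean-Mesoamerica, C Amazonia, D Dry diagonal,
# E Andes, F Atlantic Forest.
# 0.5 = contiguous regions; 0.1 = separated by one region or by water;
# 0.01 = separated by more than two regions, or by water plus regions;
# 0.7 = Mesoamerican lowlands <-> undeveloped northern Andes (11-7 Ma only).
A B C D E F
7-0
1 0.5 0.1 0.01 0.1 0.01
0.5 1 0.5 0.1 0.5 0.01
0.1 0.5 1 0.5 0.5 0.1
0.01 0.1 0.5 1 0.5 0.5
0.1 0.5 0.5 0.5 1 0.1
0.01 0.01 0.1 0.5 0.1 1
END
11-7
1 0.5 0.01 0.01 0.01 0.01
0.5 1 0.5 0.1 0.7 0.01
0.01 0.5 1 0.1 0.5 0.01
0.01 0.1 0.1 1 0.5 0.5
0.01 0.7 0.5 0.5 1 0.1
0.01 0.01 0.01 0.5 0.1 1
END
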