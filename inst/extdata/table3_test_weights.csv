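id,actual,estimated
1,238,246.2
2,239.5,232.5
3,243,226.6
4,244.5,248.1
5,246.5,252.8
6,247.5,272.6
7,249,252.8
8,250,252.6
9,250.5,236.4
10,251,261.5
11,251.5,225.7
12,252.5,268.3
13,254,247.6
14,256.5,248.9
15,259.5,274.2
16,262.5,253.4
17,263,256.3
18,264,268.7
19,264.5,274.3
20,265.5,246.8
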