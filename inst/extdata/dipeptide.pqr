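ATOM      1 N    ALA     1       0.000       0.000       0.000  -0.4157   1.8240
ATOM      2 CA   ALA     1       1.458       0.000       0.000   0.0337   1.9080
ATOM      3 C    ALA     1       2.009       1.420       0.000   0.5973   1.9080
ATOM      4 O    ALA     1       1.251       2.390       0.000  -0.5679   1.6612
ATOM      5 CB   ALA     1       1.988      -0.773      -1.199  -0.1825   1.9080
ATOM      6 N    LYS     2       3.332       1.536       0.000  -0.3479   1.8240
ATOM      7 CA   LYS     2       3.983       2.845       0.000  -0.2400   1.9080
ATOM      8 C    LYS     2       5.499       2.700       0.000   0.7341   1.9080
ATOM      9 O    LYS     2       6.030       1.591       0.000  -0.5894   1.6612
ATOM     10 NZ   LYS     2       4.512       5.510       1.583   0.9000   1.8240
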