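# tiny hand-written OpenDX scalar grid (2x2x2)
object 1 class gridpositions counts 2 2 2
origin 0.0 0.0 0.0
delta 1.0 0.0 0.0
delta 0.0 1.0 0.0
delta 0.0 0.0 1.0
object 2 class gridconnections counts 2 2 2
object 3 class array type double rank 0 items 8 data follows
1.0 2.0 3.0
4.0 5.0 6.0
7.0 8.0
attribute "dep" string "positions"
object "regular positions regular connections" class field
component "positions" value 1
component "connections" value 2
component "data" value 3
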