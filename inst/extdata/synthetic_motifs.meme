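MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF YY1
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.100000 0.700000 0.100000 0.100000
 0.600000 0.140000 0.130000 0.130000
 0.600000 0.130000 0.140000 0.130000
 0.100000 0.100000 0.700000 0.100000
 0.940000 0.020000 0.020000 0.020000
 0.020000 0.020000 0.020000 0.940000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.130000 0.600000 0.140000 0.130000
 0.150000 0.150000 0.550000 0.150000

MOTIF ETS
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.600000 0.140000 0.130000 0.130000
 0.100000 0.700000 0.100000 0.100000
 0.120000 0.640000 0.120000 0.120000
 0.020000 0.020000 0.940000 0.020000
 0.020000 0.020000 0.940000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.940000 0.020000 0.020000 0.020000
 0.130000 0.130000 0.610000 0.130000

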