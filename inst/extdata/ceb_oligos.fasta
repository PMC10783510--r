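>CEBwt
AAGGGTGGGTGTAAGTGTGGGTGGGT
>CEBm0A
AAGGGTGGGTAAAAAAATGGGTGGGT
>CEBm0T
AAGGGTGGGTTTTATTTTGGGTGGGT
>CEBm1
AAGGGTGGGTCCCAGTGTGGGTGGGT
>CEBm2
AAGGGTGGGTCCCACTGTGGGTGGGT
>CEBm3
AAGGGTGGGTCCCACCGTGGGTGGGT
>CEBm4
AAGGGTGGGTCCCACCCTGGGTGGGT
>CEBm5
AAGGGTGGGTCCCACCCTGGGTGGGTCCCA
>CEBm6
AAGGGTGGGTCCCAGTGTGGGTGGGTCCCACCCA
>CEBm7
AAGGGTGGGTCCCACCCTGGGTGGGTCCCACCCA
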