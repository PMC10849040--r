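# Eight-site FMO Hamiltonian of Prosthecochloris aestuarii (cm^-1).
# Diagonal: average site energies relative to site 3; off-diagonal:
# inter-site couplings.  Upper triangle as published, mirrored here.
310    -94.8    5.5    -5.9    7.1   -15.1  -12.2   39.5
-94.8   230    29.8     7.6    1.6    13.1    5.7    7.9
5.5     29.8    0     -58.9   -1.2    -9.3    3.4    1.4
-5.9     7.6  -58.9   180    -64.1   -17.4  -62.3   -1.6
7.1      1.6   -1.2   -64.1  405      89.5   -4.6    4.4
-15.1   13.1   -9.3   -17.4   89.5   320     35.1   -9.1
-12.2    5.7    3.4   -62.3   -4.6    35.1  270    -11.1
39.5     7.9    1.4    -1.6    4.4    -9.1  -11.1  505
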