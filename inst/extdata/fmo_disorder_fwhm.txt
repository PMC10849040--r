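# Gaussian static-disorder widths of the FMO site energies (cm^-1),
# full width at half maximum, sites 1-8.
60 100 60 60 120 120 120 100
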