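chrom	phys_len	gen_len
A01	29595527	106.84
A02	31442979	98.25
A03	38154160	111.76
A04	21928416	71.58
A05	28493056	108.5
A06	29167992	98.83
A07	28928902	90.36
A08	22981702	71.88
A09	45156810	115.21
A10	20725698	72.11
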