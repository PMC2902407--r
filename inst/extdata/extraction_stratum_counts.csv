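stratum,RecoverAll_FFPE,mirVana_frozen,TRIzol_frozen
low,125,96,90
medium,141,122,122
high,118,166,172
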