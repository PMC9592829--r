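fingerprint,ba_average
Morgan,0.697
MACCS,0.684
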