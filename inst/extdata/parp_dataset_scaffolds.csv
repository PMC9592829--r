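target,uniprot,n_compounds,n_scaffolds,pct
PARP-1,P09874,3777,663,17.55
PARP-2,Q9UGN5,412,110,26.70
PARP-5A,O95271,849,175,20.61
PARP-5B,Q9H2K2,732,159,21.72
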