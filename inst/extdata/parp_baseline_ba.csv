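model,fingerprint,ba
DNN,Morgan,0.703
XGBoost,Morgan,0.700
SVM,Morgan,0.692
RF,Morgan,0.655
LR,Morgan,0.735
XGBoost,MACCS,0.691
DNN,MACCS,0.681
SVM,MACCS,0.680
RF,MACCS,0.673
LR,MACCS,0.695
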