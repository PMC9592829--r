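target,acc,f1,ba,se,sp,mcc,auc
PARP-1,0.897,0.938,0.788,0.952,0.623,0.615,0.911
PARP-2,0.795,0.843,0.774,0.871,0.677,0.558,0.888
PARP-5A,0.871,0.923,0.728,0.958,0.497,0.525,0.877
PARP-5B,0.886,0.934,0.723,0.962,0.483,0.525,0.876
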