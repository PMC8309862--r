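model,w,TN,FP,FN,TP,accuracy,precision,recall,f1,numD_HA_w,FP_w,numR_HA,AD_HA_w,false_rate
AdaBoost,1,9,7,2,6,0.625,0.461538461538462,0.75,0.571428571428571,6,7,8,0.75,0.875
AdaBoost,3,9,7,2,6,0.625,0.461538461538462,0.75,0.571428571428571,9,4,8,1.125,0.5
AdaBoost,5,9,7,2,6,0.625,0.461538461538462,0.75,0.571428571428571,9,4,8,1.125,0.5
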