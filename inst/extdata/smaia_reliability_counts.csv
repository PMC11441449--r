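group,condition,session,color,n,zero_fl,low_fl,high_fl,rodfree_detected,rodfree_n
choroideremia,scotopic,test1,cyan_505nm,20,13,4,3,17,20
choroideremia,scotopic,test1,red_627nm,20,12,7,1,NA,NA
choroideremia,scotopic,test2,cyan_505nm,14,10,4,0,13,14
choroideremia,scotopic,test2,red_627nm,14,10,4,0,NA,NA
choroideremia,mesopic,test1,white,16,12,3,1,NA,NA
healthy,scotopic,test1,cyan_505nm,21,14,5,2,17,21
healthy,scotopic,test1,red_627nm,21,16,3,2,NA,NA
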