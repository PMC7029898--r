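sample_id,condition,grade,tailing_factor,predicted_grade,probability
4,control,Scu 1,1.182,Scu 1,1
3,exploded,Scu 1,1.197,Scu 1,1
4,control,Scu 1,1.209,Scu 1,1
5,control,Scu 2,1.269,Scu 1,1
3,exploded,Scu 1,1.306,Scu 1,1
3,exploded,Scu 1,1.403,Scu 1,1
5,control,Scu 1,1.434,Scu 1,1
4,control,Scu 1,1.451,Scu 1,1
2,exploded,Scu 1,1.521,Scu 1,0.667
1,exploded,Scu 1,1.570,Scu 1,0.667
2,exploded,Scu 1,1.687,Scu 2,0.667
3,exploded,Scu 2,1.825,Scu 2,0.667
1,exploded,Scu 2,1.883,Scu 2,0.667
1,exploded,Scu 2,1.901,Scu 2,0.667
1,exploded,Scu 2,2.365,Scu 3,0.667
1,exploded,Scu 3,2.473,Scu 3,0.667
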