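block,row_label,col_label,count,test
sex,stable,male,45,pearson
sex,stable,female,20,pearson
sex,infection,male,25,pearson
sex,infection,female,25,pearson
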