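patient_id,gene,primary_call,metastasis_call,normal_call
p01,BNC1,unmethylated,methylated,
p02,BNC1,methylated,methylated,
p03,BNC1,unmethylated,methylated,
p04,BNC1,unmethylated,methylated,
p05,BNC1,unmethylated,methylated,
p06,BNC1,unmethylated,methylated,
p07,BNC1,unmethylated,methylated,
p08,BNC1,unmethylated,methylated,
p09,BNC1,failed,methylated,
p10,BNC1,failed,methylated,
p01,GALNT9,unmethylated,methylated,
p02,GALNT9,unmethylated,unmethylated,
p03,GALNT9,unmethylated,methylated,
p04,GALNT9,unmethylated,unmethylated,
p05,GALNT9,unmethylated,methylated,
p06,GALNT9,failed,methylated,
p07,GALNT9,failed,unmethylated,
p08,GALNT9,failed,unmethylated,
p09,GALNT9,failed,methylated,
p10,GALNT9,failed,unmethylated,
p01,CCDC8,methylated,methylated,unmethylated
p02,CCDC8,methylated,methylated,
p03,CCDC8,methylated,methylated,
p04,CCDC8,methylated,methylated,
p05,CCDC8,methylated,methylated,
p06,CCDC8,methylated,methylated,
p07,CCDC8,methylated,methylated,
p08,CCDC8,methylated,methylated,
p09,CCDC8,methylated,methylated,
p10,CCDC8,methylated,methylated,
p11,CCDC8,unmethylated,unmethylated,
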