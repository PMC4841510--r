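disease_name,region,year,deaths
Ischemic heart disease,Western Europe,2000,640000
Lung cancer,Western Europe,2000,180000
Colorectal cancer,Western Europe,2000,110000
Breast cancer,Western Europe,2000,75000
Stomach cancer,Western Europe,2000,55000
Prostate cancer,Western Europe,2000,52000
Pancreatic cancer,Western Europe,2000,40000
Leukemia,Western Europe,2000,32000
Bladder cancer,Western Europe,2000,30000
Ovarian cancer,Western Europe,2000,24000
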