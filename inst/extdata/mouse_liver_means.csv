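organ,time_days,value,value_type,n,sd,arm
liver,1,33.11,percent_id,5,NA,EGCG-AuNP
liver,7,16.18,percent_id,5,NA,EGCG-AuNP
liver,14,21.23,percent_id,5,NA,EGCG-AuNP
liver,28,7.49,percent_id,8,NA,EGCG-AuNP
liver,56,8.18,percent_id,7,NA,EGCG-AuNP
liver,1,19.28,percent_id,6,NA,Curc-AuNP
liver,7,23.88,percent_id,6,NA,Curc-AuNP
liver,14,15.85,percent_id,6,NA,Curc-AuNP
liver,28,9.38,percent_id,8,NA,Curc-AuNP
liver,56,7.92,percent_id,8,NA,Curc-AuNP
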