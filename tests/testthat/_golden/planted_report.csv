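"gene","region","site","site1_span","site1_seq","rvd1","spacer_seq","site2_span","site2_seq","site2_revcomp","rvd2","enzyme","prototype","buffer","buffer_score","strand","position","second_cut_rel"
"planted_example","A1",1,"128-142(15)","GCCGGCGCCGGCGCC","NN|HD|HD|NN|NN|HD|NN|HD|HD|NN|NN|HD|NN|HD|HD","GCGGATGCATGGCGG","158-172(15)","GGCGCCGGCGCCGGC","GCCGGCGCCGGCGCC","NN|HD|HD|NN|NN|HD|NN|HD|HD|NN|NN|HD|NN|HD|HD","NsiI","NsiI","standard",2,"+",147,
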