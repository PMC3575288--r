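talenforge TALEN design report
sites: 1

== planted_example A1 Site 1 ==
TAL1    128-142(15)  GCCGGCGCCGGCGCC
Spacer  GCGGATGCATGGCGG
TAL2    158-172(15)  GGCGCCGGCGCCGGC
TAL2rc  GCCGGCGCCGGCGCC
RVD1    NN	HD	HD	NN	NN	HD	NN	HD	HD	NN	NN	HD	NN	HD	HD
RVD2    NN	HD	HD	NN	NN	HD	NN	HD	HD	NN	NN	HD	NN	HD	HD
Enzymes (name prototype score position second_cut):
  NsiI	NsiI	2	147	

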