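CC   Bairoch-dialect restriction enzyme fixture, version synthetic-1.0
CC   Hand-written subset of well-known commercially available enzymes.
CC   RS lines carry recognition sites with cut annotation (caret or
CC   parenthesized offsets); CR lines carry single-letter supplier codes.
//
ID   AatII
ET   RM2
RS   GACGT^C;
CR   N;
//
ID   AflII
ET   RM2
RS   C^TTAAG;
CR   N;
//
ID   AgeI
ET   RM2
RS   A^CCGGT;
CR   NR;
//
ID   AlwNI
ET   RM2
RS   CAGNNN^CTG;
CR   N;
//
ID   ApaI
ET   RM2
RS   GGGCC^C;
CR   BNR;
//
ID   AvrII
ET   RM2
RS   C^CTAGG;
CR   N;
//
ID   BamHI
ET   RM2
RS   G^GATCC;
CR   BFNQR;
//
ID   BglII
ET   RM2
RS   A^GATCT;
CR   BFNR;
//
ID   BstXI
ET   RM2
RS   CCANNNNN^NTGG;
CR   BFN;
//
ID   ClaI
ET   RM2
RS   AT^CGAT;
CR   BN;
//
ID   DdeI
ET   RM2
RS   C^TNAG;
CR   N;
//
ID   DraI
ET   RM2
RS   TTT^AAA;
CR   BFNR;
//
ID   DraIII
ET   RM2
RS   CACNNN^GTG;
CR   N;
//
ID   EcoRI
ET   RM2
RS   G^AATTC;
CR   BFNQR;
//
ID   EcoRV
ET   RM2
RS   GAT^ATC;
CR   BFNR;
//
ID   HaeIII
ET   RM2
RS   GG^CC;
CR   BFNR;
//
ID   HindIII
ET   RM2
RS   A^AGCTT;
CR   BFNQR;
//
ID   HinfI
ET   RM2
RS   G^ANTC;
CR   BFNR;
//
ID   HpaI
ET   RM2
RS   GTT^AAC;
CR   BNR;
//
ID   KpnI
ET   RM2
RS   GGTAC^C;
CR   BFNR;
//
ID   MfeI
ET   RM2
RS   C^AATTG;
CR   N;
//
ID   MluI
ET   RM2
RS   A^CGCGT;
CR   BFN;
//
ID   MspI
ET   RM2
RS   C^CGG;
CR   BFNR;
//
ID   NcoI
ET   RM2
RS   C^CATGG;
CR   BFNR;
//
ID   NdeI
ET   RM2
RS   CA^TATG;
CR   BFNR;
//
ID   NheI
ET   RM2
RS   G^CTAGC;
CR   BFNR;
//
ID   NotI
ET   RM2
RS   GC^GGCCGC;
CR   BFNQR;
//
ID   NsiI
ET   RM2
RS   ATGCA^T;
CR   BN;
//
ID   PstI
ET   RM2
RS   CTGCA^G;
CR   BFNR;
//
ID   PvuI
ET   RM2
RS   CGAT^CG;
CR   BNR;
//
ID   PvuII
ET   RM2
RS   CAG^CTG;
CR   BFNR;
//
ID   SacI
ET   RM2
RS   GAGCT^C;
CR   BFNR;
//
ID   SalI
ET   RM2
RS   G^TCGAC;
CR   BFNR;
//
ID   ScaI
ET   RM2
RS   AGT^ACT;
CR   BFNR;
//
ID   SmaI
ET   RM2
RS   CCC^GGG;
CR   BFNQR;
//
ID   SpeI
ET   RM2
RS   A^CTAGT;
CR   BNR;
//
ID   SphI
ET   RM2
RS   GCATG^C;
CR   BFNR;
//
ID   StuI
ET   RM2
RS   AGG^CCT;
CR   BN;
//
ID   XbaI
ET   RM2
RS   T^CTAGA;
CR   BFNQR;
//
ID   XcmI
ET   RM2
RS   CCANNNNNNNNNTGG;
CR   N;
//
ID   XhoI
ET   RM2
RS   C^TCGAG;
CR   BFNQR;
//
ID   XmaI
ET   RM2
RS   C^CCGGG;
CR   N;
//
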