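raman_shift,shift_lo,shift_hi,code_health,code_lesion,assignment
484,484,484,w,s,Glycogens
516,516,516,m,s,Phosphatidylinositol
717-719,717,719,s,m,Lipid
719,719,719,s,m,Phospholipid
728,728,728,s,s,Collagen
815,815,815,s,s,Nucleic acid
820,820,820,s,s,Structural protein modes of tumors
858-863,858,863,m,s,"Tyrosine, collagen type I"
1174,1174,1174,m,m,Phenylalanine
1198,1198,1198,s,m,Tryptophan
1223,1223,1223,m,m,Collagen I
1220,1220,1220,s,s,Amide III
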