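pdb_id,sequence,description,resolution,space_group,r_free,r_factor,n_loops_printed,n_unresolved,loop_types
1K8P,d[BrU-A-G3-BrU-T-A-G3-T],Native DNA,2.40,P3(1)21,0.280,0.193,2,1,1
1KF1,d[A-G3-(T2-A-G3)3],Native DNA,2.10,P6,0.263,0.231,3,0,1;1;1
2HRI,d[T-A-G3-T2-A-G3],Porphyrin TMPyP4 complex,2.09,C222(1),0.257,0.208,2,0,2;3
3CE5,d[T-A-G3-T2-A-G3-T],Acridine complex,2.50,I4,0.213,0.184,2,0,1;7
3CCO,d[T-A-G3-T2-A-G3-T],ND complex,2.20,P6(4)22,0.303,0.257,1,0,4
3CDM,d[T-A-G3-(T2-A-G3)3],ND complex,2.10,P2(1),0.295,0.234,6,0,1;1;1;1;5;6
3IBK,r(BrU-A-G3-U2-A-G3-U),Native RNA,2.20,P3(1)21,0.231,0.216,2,1,1
3MIJ,r(U-A-G3-U2-A-G3-U),RNA acridine complex,2.60,P23,0.248,0.236,1,0,8
3QCR,d[T-A-G3-T2-A-G3-T],Acridine complex,3.20,P6(2)22,0.378,0.346,1,1,
3SC8,d[A-G3-(T2-A-G3)3],ND complex,2.30,P3(1)21,0.288,0.260,3,0,1;10;11
3T5E,d[A-G3-(T2-A-G3)3],ND complex,2.10,P6,0.282,0.245,3,0,1;1;1
3QSC,d[A-G3-T2-A-G3-T2],Salphen complex,2.40,C222,0.234,0.214,1,0,9
3QSF,d[A-G3-T2-A-G3-T2],Salphen complex,2.40,C222,0.320,0.240,1,0,9
3UYH,d[A-G3-(T2-A-G3)3],ND complex,1.95,P3(1)21,0.275,0.231,3,0,1;10;11
4DA3,d[G3-(T2-A-G3)3],ND complex,2.40,P3(1)21,0.282,0.242,3,0,1;10;12
4DAQ,d[G3-(T2-A-G3)3],ND complex,2.75,P3(1)21,0.275,0.212,3,0,1;10;12
3R6R,d[A-G3-(T2-A-G3)3],Berberine complex,2.30,P6,0.252,0.217,3,0,1;1;1
4G0F,d[A-G3-(T2-A-G3)3],Mesoporphyrin complex,2.15,P6,0.262,0.239,3,0,1;1;1
4FXM,d[A-G3-(T2-A-G3)3],Mesoporphyrin complex,1.65,P2(1)2(1)2,0.262,0.224,3,0,1;1;1
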