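loop_id,structure_id,loop_type,L1,L2,L3
1KF1-a,1KF1,1,C1'-exo,C3'-endo,C2'-endo
1KF1-b,1KF1,1,C1'-exo,C3'-endo,C2'-endo
1KF1-c,1KF1,1,C1'-exo,C3'-endo,C2'-endo
1K8P,1K8P,1,C1'-exo,C3'-endo,C2'-endo
3IBK,3IBK,1,C1'-exo,C3'-endo,C2'-endo
3CDM-a,3CDM,1,C1'-exo,C3'-endo,C2'-endo
3CDM-b,3CDM,1,C4'-exo,C3'-endo,C2'-endo
3CDM-c,3CDM,1,C1'-exo,C3'-endo,C2'-endo
3CDM-d,3CDM,1,C1'-exo,C3'-endo,C1'-exo
3CE5,3CE5,1,C1'-exo,C3'-endo,C2'-endo
3SC8,3SC8,1,C1'-exo,C3'-endo,C2'-endo
3UYH,3UYH,1,C1'-exo,C3'-endo,C2'-endo
3T5E-a,3T5E,1,C2'-endo,C3'-endo,C2'-endo
3T5E-b,3T5E,1,C1'-exo,C3'-endo,C2'-endo
3T5E-c,3T5E,1,C2'-endo,C3'-endo,C2'-endo
4DA3,4DA3,1,C1'-exo,C3'-endo,C2'-endo
4DAQ,4DAQ,1,C1'-exo,C3'-endo,C2'-endo
3R6R-a,3R6R,1,C1'-exo,C3'-endo,C2'-endo
3R6R-b,3R6R,1,C1'-exo,C3'-endo,C2'-endo
3R6R-c,3R6R,1,C4'-exo,C3'-endo,C2'-endo
4FXM-a,4FXM,1,C2'-endo,C3'-endo,C2'-endo
4FXM-b,4FXM,1,C1'-exo,C3'-endo,C2'-endo
4FXM-c,4FXM,1,C1'-exo,C3'-endo,C2'-endo
4G0F-a,4G0F,1,C2'-endo,C3'-endo,C1'-exo
4G0F-b,4G0F,1,C2'-endo,C3'-endo,C1'-exo
4G0F-c,4G0F,1,C2'-endo,C3'-endo,C2'-endo
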