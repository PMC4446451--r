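loop_id,structure_id,loop_type,L1,L2,L3
2HRI-2,2HRI,2,C3'-endo,C1'-exo,C2'-endo
2HRI-3,2HRI,3,C2'-endo,C1'-exo,O4'-endo
3CCO-4,3CCO,4,C2'-endo,C2'-endo,C4'-exo
3CDM-5,3CDM,5,C1'-endo,C2'-endo,C2'-endo
3CDM-6,3CDM,6,C2'-endo,C3'-endo,C2'-endo
3CE5-7,3CE5,7,C2'-endo,C2'-endo,C2'-endo
3MIJ-8,3MIJ,8,C3'-exo,C3'-endo,C2'-endo
3QSC-9,3QSC,9,C2'-endo,C2'-endo,C2'-endo
3QSF-9,3QSF,9,C2'-endo,C2'-endo,C2'-endo
3SC8-10,3SC8,10,C2'-endo,C3'-exo,C1'-exo
3SC8-11,3SC8,11,C3'-endo,C2'-exo,C4'-exo
3UYH-10,3UYH,10,C2'-endo,C2'-endo,C1'-exo
3UYH-11,3UYH,11,O4'-endo,C3'-endo,C2'-endo
4DA3-10,4DA3,10,C2'-endo,C2'-endo,C1'-exo
4DA3-12,4DA3,12,C3'-exo,C2'-endo,C1'-exo
4DAQ-10,4DAQ,10,C1'-exo,C2'-endo,C1'-exo
4DAQ-12,4DAQ,12,C4'-exo,C2'-endo,C1'-exo
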