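name,parent
BRU,U
5BU,U
UBR,U
UMS,U
CBR,C
5CM,C
BGM,G
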