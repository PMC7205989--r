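domain	length
GH13	415
GH70	805
GH3	327
GH3C	161
GH43	161
CBM6	121
CBM48	101
GH2N	180
GH2	380
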