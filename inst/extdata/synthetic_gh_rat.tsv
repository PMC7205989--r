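md5	domain	env_start	env_end
3f2a9c0d1e8b7a6f5d4c3b2a19080706	GH13	98	512
3f2a9c0d1e8b7a6f5d4c3b2a19080706	CBM48	540	640
7b6a5d4e3f2c1b0a9988776655443322	GH70	61	865
a1b2c3d4e5f60718293a4b5c6d7e8f90	GH3	25	351
a1b2c3d4e5f60718293a4b5c6d7e8f90	GH3C	380	540
c0ffee00dead00beef00123456789abc	GH43	12	172
c0ffee00dead00beef00123456789abc	CBM6	210	330
0123456789abcdef0123456789abcdef	GH2N	40	219
0123456789abcdef0123456789abcdef	GH2	250	629
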