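tss_label	amplicon_index
-431	9
-56	384
-49	391
-33	407
-13	427
9	448
60	499
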