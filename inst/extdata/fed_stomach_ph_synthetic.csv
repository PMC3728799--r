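time_h,pH
0,4.8
0.5,4.3
1,3.5
1.5,2.6
2,2.0
2.1,6.8
4,6.8
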