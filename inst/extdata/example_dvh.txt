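# kind=differential unit=Gy-w target=GTV1
# small worked-example tumor DVH: 2% of the volume under-dosed below 18.5 Gy-w
dose,volume
9.4,0.002
14.0,0.006
17.5,0.012
19.0,0.10
21.0,0.22
23.0,0.30
25.0,0.24
27.0,0.10
29.0,0.02
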