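position	strand	mod_type
24	bottom	5fC
36	bottom	5fC
42	bottom	5fC
48	bottom	5fC
22	top	5fC
28	top	5fC
34	top	5fC
46	top	5fC
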