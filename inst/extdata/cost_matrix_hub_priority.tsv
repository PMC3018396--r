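# Hub-prioritising loss matrix; rows = true class (NH,IC,PH,DH),
# columns = predicted class.
0	0.1	0.2	0.2
0.1	0	0.2	0.2
0.9	0.9	0	0.2
0.9	0.9	0.2	0
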