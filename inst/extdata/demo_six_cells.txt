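# Six roots showing the full event vocabulary: an untouched cell, a normal
# division, a death, a division in four, a division in six whose daughters
# all fuse back together, and a field exit. Survivors are closed by the
# auto-end rule at frame 432.
0 begin C1
0 begin C2
0 begin C3
0 begin C4
0 begin C5
0 begin C6
71 out C6
74 div C5 C5.1 C5.2 C5.3 C5.4 C5.5 C5.6
89 div C4 C4.1 C4.2 C4.3 C4.4
228 div C2 C2.1 C2.2
345 death C3
376 fusion C5.1 C5.2 C5.3 C5.4 C5.5 C5.6 C5.7
432 end C1
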