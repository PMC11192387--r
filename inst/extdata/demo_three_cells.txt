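# Three hand-annotated cells over a 3-day movie (432 frames, 10 min/frame).
# C1 dies untouched; C2 divides into three, one daughter leaves the field,
# two fuse and the product dies; C3 survives to the end.
0 begin C1
0 begin C2
0 begin C3
112 div C2 C2.1 C2.2 C2.3
250 death C1
287 out C2.2
380 fusion C2.1 C2.3 C2.4
410 death C2.4
432 end C3
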