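{"dab":[0.268147521716579,0.570313758874813,0.776427152433078],"hematoxylin":[0.650028601887738,0.704030978044566,0.286012584830605]}
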