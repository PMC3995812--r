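{"blue":[0.740148044414805,0.620124037212404,0.260052015605202],"nuclear_fast_red":[0.210199784738371,0.720684976245845,0.660627894892025]}
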