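# Null-scenario rejection study (type-I error) at a desk-test scale.
kind: rejection
n-cycles: 200
beta-up: 0
beta-ep2: 0
reps: 5
alpha: 0.05
seed: 7
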