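# synthetic toy regulatory circuit (hand-written example, not from any
# published model): S is an external signal, A and B a mutual-inhibition
# pair gated by S, C an AND-gated readout
targets, factors
A, S & !B
B, !A & !S
C, A & B | A & S
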