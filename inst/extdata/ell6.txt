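# order-6 ell-graph: K4 split into halves {0,1} and {2,3},
# extra vertex 4 joined to {0,1} and 5; extra vertex 5 joined to {2,3} and 4
0 1
0 2
0 3
1 2
1 3
2 3
0 4
1 4
2 5
3 5
4 5
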