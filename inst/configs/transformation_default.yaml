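# Default full-reactivation protocol: 25 repetitions of 10 reactivations on a
# highly segregated 128-node network, four communities.
N: 128
C: 4
Z0: 0.01
Int: 0.3
theta: 0.4
reactivations: 10
runs: 25
seed: 1
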