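# Preserved-identity protocol: cue only one community for 15 reactivations,
# across initial degrees of integration, and track its tightness.
N: 128
C: 4
Z0: [0.01, 0.1, 0.3, 0.6]
Int: 0.3
theta: 0.4
reactivations: 15
runs: 25
seed: 1
protocol: single-community
community: 0
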