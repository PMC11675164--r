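# Z-deltaL phase-space trajectories across excitability thresholds at
# fixed intensity.
N: 128
C: 4
Z0: 0.01
Int: 0.3
theta: [0.2, 0.3, 0.4, 0.5, 0.6]
reactivations: 10
runs: 25
seed: 1
protocol: full
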