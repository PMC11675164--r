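# Intensity generalization: the full turn-on intensity scan at N = 128.
N: 128
C: 4
Z0: 0.01
Int: [0.1, 0.12, 0.14, 0.16, 0.18, 0.2, 0.22, 0.24, 0.26, 0.28, 0.3,
      0.32, 0.34, 0.36, 0.38, 0.4, 0.42, 0.44, 0.46, 0.48, 0.5, 0.52,
      0.54, 0.56, 0.58, 0.6, 0.62, 0.64, 0.66, 0.68, 0.7]
theta: 0.4
reactivations: 10
runs: 25
seed: 1
protocol: full
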