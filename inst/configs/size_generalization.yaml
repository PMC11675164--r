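# Size generalization: the seven standard sizes, each with its designated
# initial degree of integration (paired grid, not a Cartesian product).
Int: 0.3
theta: 0.4
C: 4
reactivations: 10
runs: 25
seed: 1
protocol: full
grid:
  - { N: 16,   Z0: 0.3 }
  - { N: 32,   Z0: 0.09 }
  - { N: 64,   Z0: 0.02 }
  - { N: 128,  Z0: 0.01 }
  - { N: 256,  Z0: 0.001 }
  - { N: 512,  Z0: 0.0004 }
  - { N: 1024, Z0: 0.0001 }
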