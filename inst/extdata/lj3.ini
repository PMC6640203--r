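# Three-atom Lennard-Jones cluster, reduced units.  The published swarm
# parameterization is the zero-config default; only the budget is trimmed.

[cluster]
elements = C C C

[backend]
name = lennard_jones
epsilon = 1.0
sigma = 1.0

[pso]
max_iter = 300
n_restarts = 4
seed = 1

[executor]
n_workers = 1
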