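# Small budgets for a quick three-method comparison on the 3-atom cluster.

[cluster]
elements = C C C

[backend]
name = lennard_jones

[pso]
max_iter = 150
n_restarts = 2
seed = 1

[sa]
T0 = 0.5
alpha = 0.97
steps_per_T = 300
step_size = 0.01
max_steps = 20000
seed = 1

[bh]
max_hops = 25
seed = 1
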