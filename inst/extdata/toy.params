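# Toy gene circuit: signal maturation, product/inhibitor genes, annihilation
# State in arbitrary-units/volume, time in minutes.
model_id: toy
k_1: 1            # 1/(arb.u. min)  generation rate constant of intracellular signal molecule
k_dS: 0.994       # 1/min           degradation rate constant of intracellular signal molecule
k_p: 50           # arb.u./(volume min)  generation rate constant of product
k_dX: 0.994       # 1/min           degradation rate constant of product
k_u: 1            # 1/min           uptake rate of inhibitor
k_dI: 0.994       # 1/min           degradation rate constant of intracellular inhibitor
k_i: 80           # arb.u./(volume min)  generation rate constant of extracellular inhibitor
P: 6              # arb.u.          membrane protein
mu: 0.006         # 1/min           net specific growth rate of cells
V_cell: 1E-15     # volume          volume per cell
theta_i: 0.5      # -               configuration factor of xi gene
theta_p: 2.4      # -               configuration factor of xp gene
gamma: 1000       # 1/(arb.u. min)  signal-inhibitor annihilation rate
                  #                 (large finite surrogate for the fast
                  #                 irreversible binding reaction)
phi_cell: 0.5     # -               cell number density times per-cell volume: sets
                  #                 the extracellular turnover rate phi*k_u; matched
                  #                 to the pCF10 system convention
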