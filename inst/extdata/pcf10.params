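# pCF10 pheromone-inducible conjugation switch: rate constants
# Intracellular state in nM, time in seconds.
model_id: pcf10
K_1,1: 0.0084       # nM/s   transcription rate of prgQ, DNA in loop form
K_1,2: 0.0876       # nM/s   transcription rate of prgQ, DNA in un-loop form
K_1,3: 0.0125       # nM/s   transcription rate of Anti-Q, DNA in loop form
K_1,4: 0.0014       # nM/s   transcription rate of Anti-Q, DNA in un-loop form
K_1,5: 0.01         # 1/s    generation rate of PrgB for first order reaction
K_1,6: 0.005        # 1/s    generation rate of extracellular inhibitor, iCF10
K_1,7: 0.00155      # nM/s   basic generating rate of membrane protein PrgB
K_1,8: 12.00        # nM     threshold concentration of Q_L
K_1,9: 0.0031       # nM/s   rate constant of generating membrane protein PrgB
K_2,6: 0.001        # 1/s    importation rate of inhibitor, iCF10
K_2,8: 2.57E-04     # 1/s    importation rate of pheromone, cCF10
K_3,5: 0.0443       # 1/nM   equilibrium constant of Q_PRE and Anti-Q reaction
K_3,8: 1.00E06      # -      equilibrium constant of DNA binding reaction
K_3,9: 12.00        # 1/nM   constant of sigmoid function for Q_L to PrgB
K_4,1: 0.001        # 1/s    degradation rate of Q_s mRNA
K_4,2: 0.100        # 1/s    degradation rate of Q_L mRNA
K_4,3: 0.0001359    # 1/s    degradation rate of Anti-Q RNA
K_4,5: 1.00E-06     # 1/s    degradation rate of extracellular inhibitor, iCF10
K_4,6: 1.00E-06     # 1/s    degradation rate of intracellular inhibitor, iCF10
K_4,8: 1.00E-06     # 1/s    degradation rate of intracellular pheromone, cCF10
K_4,9: 1.00E-06     # 1/s    degradation rate of PrgB protein
mu_hat: 0.0002567   # 1/s    net specific growth rate of donor cells
n: 4                # -      order of DNA binding reaction
phi_cell: 0.5       # -      cell volume fraction (held constant)
V_cell: 5.0E-15     # L      per-cell volume; sets CLE noise scale so that the
                    #        off-state PrgB level (~6 nM) is ~18 molecules,
                    #        inside the published 14-35 molecules-per-cell
                    #        off-state estimate
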