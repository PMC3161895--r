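---
title: "Population-balance modelling of stochastic gene expression: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-balance modelling of stochastic gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmcell)
```

## The scientific question

Flow-cytometry readouts of clonal microbial populations are often bimodal:
two subpopulations, one with low and one with high expression of a reporter
protein. The textbook explanation is deterministic bistability of the
underlying gene circuit — two stable steady states, each collecting part of
the population. `pbmcell` implements the modelling machinery needed to test
that explanation at the population scale: ensembles of stochastic
single-cell models coupled through a shared extracellular environment (a
sample-path solution of a population balance model, PBM), next to the
conventional *isolated* single-cell stochastic model in which each cell
owns a private copy of its environment. Running both on the same circuits
shows that bistability is neither necessary nor sufficient for bimodality:

* a monostable circuit with heterogeneous plasmid copy numbers produces a
  bimodal population (`run_recipe("fig4")`, `run_recipe("fig9")`);
* a bistable circuit simulated as interacting cells produces a unimodal
  population, and an artificially bimodal initial population merges into
  one mode (`run_recipe("fig5")`, `run_recipe("fig6")`, `run_recipe("fig8")`).

Two circuits are shipped: the pheromone-inducible conjugation switch of the
*Enterococcus faecalis* plasmid pCF10, and a minimal "toy" circuit with the
same architectural ingredients (an imported signal, a secreted antagonist,
a reporter).

## The pCF10 single-cell model

State vector (nM): `Q_S`, `Q_L` (short and long *prgQ* transcripts),
`AntiQ` (antisense RNA), `I_i` (intracellular inhibitor peptide iCF10),
`C_i` (intracellular pheromone cCF10), `B` (surface protein PrgB, the
conjugation readout). Parameters are the packaged `load_parameters("pcf10")`
table; all rates per second.

**DNA configuration.** The *prgQ* promoter is repressed when
iCF10-loaded PrgX tetramers hold the DNA in a loop; pheromone-loaded PrgX
relieves the loop. The looped fraction is modelled as a competitive
exchange equilibrium of binding order `n = 4`:

$$ f_{loop}(I_i, C_i) \;=\; \frac{1}{1 + K_{3,8}\,(C_i/I_i)^{\,n}} , $$

with `K_3,8 = 1e6` (dimensionless) and the conventions `f = 0` when
`I_i = 0` and `f = 1` when `C_i = 0, I_i > 0`. *This algebraic form is a
reconstruction*: it is constrained by the mechanism (monotone increasing in
inhibitor, decreasing in pheromone, saturating at 0 and 1, fourth-order
binding, dimensionless equilibrium constant) but its exact shape is the
package's choice, fixed once against the published steady-state and
population behaviour (bistable window containing 13.5 nM at copy number 5;
single branch when `K_4,2 = K_4,1`; complete population switching at 30 nM
under copy-number heterogeneity). It is the largest single reconstruction
risk in the package.

**Transcription and antisense titration.** Both *prgQ* and Anti-Q
transcription are loop-weighted mixtures scaled by plasmid copy number $k$:
$T_Q = k\,[K_{1,1} f + K_{1,2}(1-f)]$,
$T_A = k\,[K_{1,3} f + K_{1,4}(1-f)]$. Nascent transcript bound by Anti-Q
(equilibrium `K_3,5`, bound fraction $b = K_{3,5}A/(1+K_{3,5}A)$) matures
into `Q_S` and consumes one Anti-Q; free transcript matures into `Q_L`.
Every species carries first-order degradation (`K_4,*`) and growth dilution
(`mu_hat`).

This structure makes the published bistability-exclusion property emerge
rather than being imposed: with `K_4,2 = K_4,1` the total transcript pool
`Q_S + Q_L` — and with it inhibitor production — becomes independent of the
Anti-Q partition, the remaining environmental feedback loop is monotone
negative, and only one steady state can exist at any pheromone level
(verified numerically by `bifurcation_scan()` over 0–50 nM). With the
printed asymmetric degradation (`K_4,2 = 0.1 >> K_4,1 = 0.001`) the "on"
state destroys its transcripts — hence its own inhibitor supply — quickly,
which is the positive feedback that sustains bistability.

**PrgB production** comes in the two published variants:
sigmoid $K_{1,7} + K_{1,9}/(1+e^{-K_{3,9}(Q_L - K_{1,8})})$ (used for the
steady-state and copy-number studies) and linear $K_{1,5} Q_L$ (used for
the bistability contrast); both are always available via the `variant`
argument.

**Environment.** iCF10 is translated from both transcripts and secreted
directly: per-cell source `K_1,6 (Q_S + Q_L)`, uptake `K_2,6 I_ext`,
extracellular degradation `K_4,5`, and a dilution term `mu_hat I_ext` from
the constant-cell-volume-fraction assumption (`phi_cell = 0.5`, so molar
exchange maps one-to-one between compartments). Pheromone `C_ext` is a
held-constant boundary condition.

## The toy circuit

State (arbitrary units/volume, minutes): signal `S` (matured from a
constant add-in precursor `F` by membrane protein `P`: source `k_1 P F`),
inhibitor `I` (imported at `k_u I_ext`), product `X` (source
`k_p h_p`). `S` and `I` annihilate irreversibly (rate `gamma`, default
1e3); whichever survives sets the DNA configuration factors:
`(h_p, h_i) = (theta_p, theta_i) = (2.4, 0.5)` when `S > I`, `(1, 1)`
otherwise (ties and the empty state take the baseline; the annihilation
reaction makes the boundary measure-zero). Extracellular inhibitor obeys
`dI_ext/dt = phi (k_i h_i - k_u I_ext)` with `phi` the cell volume-fraction
equivalent; the system volume is fixed (no dilution term).

The only feedback loop runs through `h_i` and the shared inhibitor pool:
signal-dominant cells halve their inhibitor export, which lowers everyone's
uptake, which helps signal dominate. With Table values the deterministic
cell+environment system is bistable (product branches at exactly
`X = 50` and `X = 120`). Neutralizing the xi-gene factor (`theta_i = 1`)
severs the loop and provably removes bistability while leaving the product
readout responsive through `theta_p` — this is the configuration used for
the heterogeneity experiment, where five subpopulations differing in the
gene-controlled membrane protein `P in {2, 4, 6, 10, 14}` (median at the
table value 6) split cleanly into the two product modes according to
whether `k_1 P F` exceeds the fixed inhibitor influx `k_i/k_u = 80`.
The values straddle that threshold with every class at least two noise
standard deviations clear of it, so the class identity — not boundary
chatter — decides each cell's mode.

## Stochastic machinery

**Chemical Langevin noise.** Each reaction channel contributes its rate to
the diffusion term: per species, amplitude
$a_s = \sqrt{\sum_c \nu_{sc}^2 r_c / \Omega}$. The volume factor converts
concentration to molecule counts: for pCF10, `Omega = 1e-9 N_A V_cell`
molecules per nM; for the toy model the printed per-cell volume `1e-15`
is read as the unit volume, i.e. one arbitrary unit/volume equals one
molecule per cell (`Omega = V_cell/1e-15 = 1`). Growth dilution is volume
expansion, not a reaction, and carries no noise. Noise masks reproduce the
published computational restrictions: `"protein"` (PrgB only) for the
copy-number study, `"protein_peptides"` (PrgB, iCF10, cCF10 — and, in the
isolated-cell model, the environment exchange channels) for the
bistability contrast.

**Per-cell volume.** The pCF10 tables do not print `V_cell`. The package
default is `5e-15` L, anchored to the published estimate that off-state
PrgB amounts to roughly 14–35 molecules per cell: the off-state level under
the table rates is ~6 nM, and `concentration_to_copies(6, 5e-15)` is ~18
molecules, inside that range. This choice sets the noise magnitude; it is
config-exposed and everything downstream (mode structure, switching) was
checked against it once, not tuned per experiment.

**Integration.** Euler–Maruyama with diagonal noise, fixed step (`dt` is
1 s / 0.01 min by default; the packaged desk-scale recipes use 5 s for the
pCF10 ensembles, far below every deterministic relaxation time, the fastest
being `1/K_4,2 = 10` s). Each step advances all cells with the environment
frozen, then the environment from the updated ensemble (first-order Lie
splitting, matching the stepwise bookkeeping of the original method). The
toy annihilation term (`gamma S I`, stiff at `gamma = 1e3`) is split off
and integrated *exactly* over each step from its closed-form solution, so
the step size is set by the slow channels. Negative excursions are clipped
to zero and counted; runs warn when clipping exceeds 1% of steps. For the
pCF10 configurations clipping is rare (< 0.01%); for the toy model the
annihilated species sits at the zero boundary by construction and its
symmetric noise clips on ~8% of steps — expected boundary behaviour of the
CLE there, with no effect on the surviving species' balance.

**The two couplings.** `simulate_pbm()` drives one shared `I_ext` with the
*ensemble mean* of the per-cell exchange — the empirical surrogate for the
expectation integral of the population balance (Monte-Carlo error shrinks
like 1/N; the replicate-variance test verifies the scaling).
`simulate_single_cells()` gives every cell a private `I_ext` advanced by
its own, stochastic, exchange. For one cell the two couplings are the same
algorithm and produce bit-identical paths.

**Division.** Constant-number Monte Carlo: each cell divides with
probability `mu dt`; daughters inherit the intracellular state and the
plasmid copy number exactly (plasmids double just before division and split
evenly); one cell is discarded per birth. In heterogeneous-composition
runs the victim is drawn from the parent's own copy-number class (or
membrane-protein subpopulation). This preserves the class marginal that
the underlying density equation holds fixed — with a uniformly drawn
victim the composition performs a neutral Moran walk whose drift is
invisible at the original 45,000-cell scale but distorts a 1,000-cell
ensemble badly (class counts drifted from 100 each to a 21–246 range in
one 25-generation run). The exported `divide_and_resample()` keeps the
plain uniform-victim scheme; the simulators expose both via `resample`.

**Initial conditions.** pCF10 runs start from the deterministic
zero-pheromone off state (relaxed per copy-number class with the shared
environment), plus one noisy burn-in interval, before the pheromone step —
the protocol behind the published "no pheromone added" initial
distributions. Toy runs start from empty cells with the environment at its
resting balance `k_i/k_u = 80`, the state of a culture before the
precursor is added; the initial signal-versus-inhibitor race is then
noise-decided in the isolated model but consensus-decided in the PBM,
which is precisely the mechanism behind the bimodal/unimodal contrast.
With the default environment turnover the outcome is insensitive to that
initial level.

**Toy environment turnover.** Only the product `n_density * V_cell`
(a volume fraction, `phi_cell`) enters the toy environment balance, and it
only sets the turnover *rate* — steady levels are independent of it. It is
not printed; the package uses 0.5, mirroring the pCF10 convention. Much
smaller values slow the environment so far that isolated cells hover at
the dominance boundary for tens of minutes, chattering between
configurations instead of locking into modes; at 0.5 fates lock within a
couple of minutes and the published clean two-mode structure appears.

## Steady states and bistability

`find_steady_states()` closes the environment loop self-consistently
(`I_ext` is an unknown solved jointly with the cell state, its balance at
zero) and runs a multistart damped Newton search in log coordinates —
which enforces positivity and matches the log-uniform start sampling
(default 200 starts over `[1e-6, 1e4]`) — with finite-difference Jacobians
(relative step 1e-6), a trust region of 5 log-units per step, and step
halving until the residual decreases. Roots are deduplicated at relative
max-norm radius 1e-4 and classified by the eigenvalues of the coupled
Jacobian: stable when every real part is below −1e-10, marginal (reported,
never silently binned) when the leading real part sits within ±1e-10.
Every reported state satisfies `max|drift| < 1e-10` (tested against 1e-9).
`bifurcation_scan()` repeats the census over a monotone control grid and
reports the maximal contiguous bistable interval; no arclength
continuation is attempted — a grid census is all the scientific claims
need. An empty census is a diagnosed result, not an error.

The deterministic toy model's configuration factors are step functions, so
its Jacobian is taken on the smooth branch each root occupies; roots sit
well away from the `S = I` boundary (the annihilation reaction guarantees
this), so the classification is unambiguous.

## Distribution diagnostics

`count_modes()` uses a Gaussian KDE (Silverman bandwidth) and counts local
maxima whose *topographic prominence* — height above the key saddle
separating them from a taller maximum — is at least 5% of the global
density maximum. Prominence, not raw height, is what makes the label
robust: shallow ripples on one hump are not modes, while a genuinely
separated 10% subpopulation is. The label is deterministic and invariant
under affine rescaling.

The "on" state is not defined numerically in the source material;
`on_off_threshold()` ties it to the model's own structure: the log-scale
midpoint between the off- and on-branch PrgB levels where the scan is
bistable, otherwise the geometric midpoint between the lowest and highest
stable PrgB across the control grid (for the monostable heterogeneity
study this gives ~10.4 nM between the 6-nM off and 18-nM on plateaus).
Copy number 5 — the population mean — anchors the scan used for
heterogeneous ensembles.

`stationarity_check()` splits the trailing 60% of the snapshot series into
four windows and requires the windowed mean and standard deviation of the
readout to change by less than 5% between consecutive windows — the
pseudo-steady-state criterion for runs that, strictly, have no stationary
distribution.

## What the simulations do and do not emulate

The ensembles are the study's own synthetic conditions: printed rate
tables, copy numbers uniform on 1..9 (mean 5), constant pheromone, a
well-mixed shared environment, constant population density. Passing the
packaged checks therefore demonstrates internal reproduction of the
modelling claims — not agreement with wet-lab measurements. Real
populations add biology the model deliberately omits: growth-rate
dependence on expression state, non-instantaneous plasmid replication and
uneven partitioning, spatial structure (biofilms are the regime where the
isolated-cell picture may actually apply), transcriptional bursting beyond
the Langevin approximation, and measurement noise. The per-cell volumes
and the toy environment turnover are reconstruction choices (above), so
absolute time scales and noise magnitudes are indicative rather than
calibrated.

## Problem sizes

The packaged experiments run at desk scale: 1,000–2,000 cells instead of
the original 30,000–45,000 (`full = TRUE` on `run_recipe()` restores
those), horizons of 1.2–2.0 × 10^5 s (pCF10, several times the slowest
~3,900 s relaxation) and 500 min (toy), with `dt = 5` s / 0.01 min. The
mean-field property (replicate variance of the shared environment falling
like 1/N) is what justifies the reduction: modality and threshold
conclusions are driven by per-class deterministic structure plus per-cell
noise, not by ensemble size, and the suite checks them at 1,000 cells with
fixed seeds.

## Known limitations

* The algebraic forms of the DNA-loop fraction and, to a lesser degree,
  the transcript-partition step are reconstructions constrained by
  mechanism and published behaviour, not transcriptions of printed
  algebra; quantitative details away from the validated regimes (e.g.
  exact fold positions far from 13.5 nM) inherit that uncertainty.
* The chemical Langevin description degrades near zero copy numbers; the
  toy model's annihilated species lives at that boundary and is handled by
  clipping.
* Euler–Maruyama is weak order 1; results at the default steps were
  checked against halved steps and a stiff ODE oracle, but very stiff
  user-supplied parameterizations should reduce `dt`.
* The constant-number scheme models "appropriate dilution"; it does not
  conserve lineages, so lineage statistics are out of scope.
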