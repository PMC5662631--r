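---
title: "Models and methods: basal-ganglia network simulation with a lesionable MSN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: basal-ganglia network simulation with a lesionable MSN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bgnetsim)
```

# Scope

`bgnetsim` simulates a cortico-basal-ganglia-thalamic circuit built from
conductance-based Hodgkin-Huxley neurons: thalamocortical relay (TH),
subthalamic (STN), external and internal pallidal (GPe, GPi), cortical
regular-spiking pyramidal (PY) and dopaminergic (DA) cells, plus one
multi-compartment medium spiny neuron (MSN) per striatal pathway (D1
direct, D2 indirect). The package's scientific purpose is to quantify how
two striatal lesions -- dendritic spine loss and dendritic tree
degeneration -- and the loss of dopaminergic neurons modulate the
fidelity with which the thalamus relays basal-ganglia output, measured
by the error index (EI).

# Cell models

## Single-compartment cells

TH, STN, GPe and GPi follow the Rubin-Terman family of basal-ganglia
models: leak, Na, K, low-threshold T-type Ca currents, plus
high-threshold Ca and a calcium-gated after-hyperpolarization (AHP)
current in STN/GPe/GPi. The pyramidal cell is the Traub-kinetics
regular-spiking cortical neuron with an M-type slow potassium current
(spike-frequency adaptation) and a small high-threshold Ca current. The
dopaminergic cell is a soma-only pacemaker carrying fast Na, A-type,
delayed-rectifier and SK potassium currents, T/N/L-type Ca currents, Na
and Ca pump currents and three leaks (Na, K, Ca).

All parameters live in `cell_params()` (uF/cm2, mS/cm2, mV, ms,
uA/cm2). The published network this package models defers its
cell-level constants to an unavailable supplementary table, so the
package's parameter sets were assembled from the cited source-model
families and then calibrated *once* against the cell-level phenotypes
those sources describe:

* TH fires no spikes in 2 s at rest and rebound-bursts after release
  from hyperpolarization;
* STN discharges spontaneously at a low rate (about 16 Hz here),
  faster under excitation, slower under inhibition;
* GPe/GPi are silent at zero bias and fire tonically in the tens of Hz
  when biased;
* PY shows monotonically lengthening inter-spike intervals under a
  sustained step;
* DA pacemakes tonically near 4 Hz with near-zero ISI dispersion.

Two DA-cell choices deserve note: the fast-Na activation/inactivation
pair was placed (m at -38 mV, h at -48 mV) so that the window supports
regenerative firing from the pacemaker depolarization, and SK gating
uses a Hill-4 calcium dependence with fast clearance so that the
subthreshold Ca window current does not latch the cell silent. Both are
calibration decisions recorded here because the original DA parameter
table is not reproducible from the main text.

The GPe balance equation carries its constant bias with a minus sign,
exactly as printed in the source model family; the default bias is
therefore negative (`i_appgpe = -1`) to produce net depolarizing drive.

## The medium spiny neuron

The MSN is a stylized 121-compartment tree: a soma bearing 8 primary
trunks (26 primary sections in chains of 3-4), each trunk ending in 2
secondary sections, each secondary bearing one subordinate section.
This realises simultaneously: 58 dendrite sections, 32 secondary +
subordinate sections, 8 soma-attached compartments, and 121
compartments (2 compartments per section; the first four subordinate
sections carry 3). The published description gives only these counts,
not the tree; the mapping above is this package's documented choice.

Thirty-two glutamatergic and thirty-two dopaminergic synapse sites sit
pairwise on the distal subordinate compartments -- main dendrites carry
no spines. Compartments couple by the discrete cable (Rall) terms
`(V_j - V_i)/R_ji`, with axial resistances computed from per-level
geometry (`msn_params()`; axial resistivity 100 Ohm cm). Somatic and
dendritic membranes carry the 14-channel MSN inventory plus leak
(`msn_channel_table()`): NaF, NaP, KAf, KAs, KIR, KRP (soma only), BK,
SK, CaL1.2, CaL1.3, CaN, CaQ, CaR, CaT. Kinetics are Boltzmann steady
states with constant or bell-shaped time constants and a pooled
calcium concentration gates BK/SK. Channel densities were calibrated to
the MSN phenotype: a hyperpolarized KIR-dominated down-state near
-85 mV, a high rheobase, and a monotone f-I curve without
depolarization block across the working range. Dendrites are close to
passive (weak channel densities); this makes distal dendrites a
membrane load, which is what produces the published lesion phenotype
(below).

## Lesion operators

`remove_spines(morph, ns, order)` deletes `ns` of the 32 glutamatergic
sites; under `type1_first` ordering, sites whose paired dopaminergic
site was lost to depletion (type-1) fall first. `degrade_dendrites(
morph, nd)` severs secondary/subordinate sections from their parent,
deleting each detached subtree, and counts *sections removed* against
`nd` (targets are drawn uniformly among sections whose subtree fits the
remaining budget, so the final count is exact). Fractions are `ns/32`
and `nd/32`. Removing dendrites removes membrane load, so the somatic
mean firing rate under a fixed stimulus rises monotonically with `nd`,
and the effect is position-invariant (distal versus proximal section
sets of equal size change the rate by less than the placement
variability) -- both behaviors are regression-tested.

# Synapses

AMPA, NMDA and GABA-A connections use the two-state (dual-exponential,
Exp2Syn-style) kinetics: `I = g*(h - m)*(V - E)`, both states decaying
in closed form, events incrementing both by the peak-normalizing factor
so a unitary event peaks at `h - m = 1`. Time constants: AMPA 0.5/2.5
ms, NMDA 2/100 ms (no magnesium block -- the printed model has none),
GABA 0.5/6 ms; reversals 0, 0, -80 mV. Connection weights are
dimensionless multipliers (`I_ab = g_ab * I_syn`).

Dopaminergic "synapses" onto the MSN sites are modelled as the same
two-state current with much slower kinetics (5/200 ms). This encodes
dopamine's volume-transmission character: with eight tonically
pacemaking DA cells all contacting every site (weights scaled by
1/n_da), the dopaminergic conductance is a smooth envelope whose
amplitude scales with the surviving cell count, rather than a train of
discrete events. D1 receives it as a depolarizing conductance (E = 0);
D2 as an inhibitory-shunting conductance with reversal at the down-state
potential (E = -85 mV), which divides cortical EPSPs without recruiting
the low-threshold Ca rebound that a hyperpolarizing reversal would
cause. These two choices -- slow kinetics and a shunting D2 reversal --
were made during calibration because the event-like alternative either
left depletion without effect (surviving phasic bumps remain fully
effective) or made the "inhibitory" input paradoxically excitatory by
rebound; they are the package's interpretation of dopamine being
"modulatory".

# Network

Populations default to 10 TH, 10 STN, 10 GPe, 10 GPi, 10 PY, 8 DA and
one MSN per pathway. The wiring contract (enforced by tests over many
seeds): every D1/D2 synapse site receives cortical and dopaminergic
input; each STN gets 3 cortical excitatory and 2 neighbouring-GPe
inhibitory inputs; each GPe gets 2 neighbouring GPe, every D2, and 2
STN inputs; each GPi gets every D1, 2 random GPe, 2 random STN and 1
neighbouring GPi; each TH gets 3 random GPi inputs; exactly 6 randomly
selected PY receive thalamic feedback. "Neighbouring" means ring
topology with wrap-around.

Dopamine depletion of fraction `f` removes `ceiling(f * n_da)` DA cells
(silencing all their synapses, which scales the dopamine envelope) and
marks `ceiling(32 f)` dopaminergic sites per MSN as lost, defining the
type-1 spine set. The parkinsonian flag is set for `f > 0.5`.

## Connection weights and the depleted-state phenotype

The published weight table is unavailable; weights are exposed in
`network_config()` and were calibrated once so the healthy network
reproduces the validation phenotypes (MSNs at a few Hz, GPe/GPi tonic
in the twenties of Hz, TH relaying near 10 Hz) and so depletion
produces the qualitative parkinsonian cascade: D1 activity falls (its
dopaminergic envelope drops past the knee of its dose-response), D2
activity rises (its shunt weakens), GPe falls slightly, GPi rises, and
the thalamic rate and relay quality degrade. The striato-pallidal
weights are strong (single MSNs must gate whole nuclei), and the
GPi->TH weight (2.5) puts the relay in a regime where thalamic spikes
are carried by pauses in pallidal firing, which is what makes relay
quality sensitive to the depleted state. With these study conditions
the EI ordering (depleted above normal) reproduces consistently; the
thalamic-rate drop at 50% depletion is real but of the same order as
across-trial variability at seconds-long trials, so the band-based
threshold claim reproduces only marginally -- an honest limitation of
desk-scale trials under a reconstructed weight table.

# Error index

A healthy calibration run (same seed, zero depletion, intact MSN)
provides, per thalamic cell, the reference maximum peak height above
baseline (-70 mV) and the expected-response window grid (window period
= the median inter-burst interval of the calibration run).
`classify_peaks()` then partitions the condition run's windows
exhaustively and exclusively: a window whose tallest event reaches 90%
of the reference maximum holds a normal peak; between 10% and 90% an
incomplete peak; below the 10% detection floor the window is a lost
peak (the rest state). `error_index()` is incomplete/normal. The 10%
floor doubles as the event detector's noise cutoff. Scale invariance
(multiplying heights above baseline by any positive constant) and
exhaustiveness are property-tested.

# Memristive cortical neuron

The electromagnetically driven cortical cell extends the pyramidal
model with a magnetic flux variable `phi' = k1*v - k2*phi`, a
memconductance `rho(phi) = alpha + 3*beta*phi^2` feeding back
`k*rho(phi)*(v + Ve)`, an AC field `Ve = a_e*sin(omega*t)` entering
every channel driving force, and the field-derivative term
`-a_e*omega*Cm*cos(omega*t)`. Gate kinetics evaluate at `v`, driving
forces at `v + Ve`, exactly as printed in the source equations.

Two facts about this literal model matter for interpretation. First,
substituting `u = v + Ve` shows `u` obeys an almost autonomous
equation: the AC field appears in the recorded `v` essentially as the
subtracted sinusoid plus an O(k) flux feedback and the gate-voltage
mismatch. With the default coupling (k = 0.001) and millivolt-scale
amplitudes the field therefore cannot recruit spiking at zero forcing
current, under any reading of the frequency unit -- the package
reproduces sub-threshold oscillation whose peak-to-peak amplitude is
2*a_e, and `classify_mode()` labels it SMPO (threshold 0.5 mV,
configurable; chosen below 2*a_e for the smallest published amplitude).
Reported amplitude-driven transitions to spiking would require the
unavailable supplementary parameterisation, and the acceptance test for
them fails honestly. Second, `omega` is treated as the literal angular
coefficient in `sin(omega*t)` with `t` in ms; both published values
(6.27 and 6.31) are accepted, and helpers convert physical Hz as
`2*pi*f/1000`.

Mode classification uses spike detection plus ISI statistics after a
2-s discarded transient: quiescent / SMPO (no spikes, peak-to-peak
below/above threshold), period-1 spiking (ISI coefficient of variation
< 0.15), period-n bursting (regular per-burst counts after splitting
ISIs at the geometric mean of their extremes when widely bimodal),
mixed-mode (two alternating burst sizes), chaotic (irregular
otherwise). No Lyapunov exponents are computed.

# Numerical methods

The engine advances the whole network at a fixed step (default dt =
0.025 ms). Gating variables and pooled calcium use exponential-Euler
updates; synapse states decay in closed form; single-compartment
voltages use forward Euler. MSN compartments use an exponential-Euler
update on the linearized membrane equation (total conductance and
driving-force decomposition, with axial coupling and synaptic
conductances folded into the linear term): the axial coupling of thin
distal compartments (tens of mS/cm2 equivalent) exceeds the
forward-Euler stability bound at this step, and the linearized update
is unconditionally stable, in the spirit of the implicit schemes used
by compartmental simulators. MSN gate kinetics are evaluated through
precomputed lookup tables (0.05 mV grid) for speed.

Spikes are detected online as upward crossings of -20 mV with a 2 ms
lockout. Synaptic events align to the step grid; there are no
conduction delays. The engine is bit-reproducible given a spec and
seed; the only randomness is the seeded initial-condition jitter (+-3
mV) that decorrelates otherwise identical cells. A numerical blow-up
(|v| > 200 mV) aborts with a diagnostic naming the unit.

Correctness is anchored by a dual route: every cell type's pure-R
reference right-hand side is integrated with an adaptive stiff solver
(deSolve::lsoda) on three pinned sub-threshold protocols (hold, step,
sinusoid; spontaneously active cells held hyperpolarized so the 500-ms
trajectories are smooth) and the engine must agree within 1 mV
sup-norm; a dt-halving convergence check bounds discretisation error on
a sub-threshold reference run.

# Problem sizes used by the tests

Unit and property tests run seconds-long simulations (0.3-3 s) at the
default populations. The depleted-state ordering uses 10 seeded 3-s
trials per condition; lesion trends use 3 seeds x 5 grid points x 2-s
trials; mode classification uses 12-s traces. These sizes are the
package's desk-scale choice: they keep the full suite in minutes while
leaving every contract expressible. Paper-faithful 16-s, 10-trial runs
are available through the same functions by changing `duration` and
`trials`.

# What the synthetic inputs do and do not show

The synthetic-trace generator (`generate_trace()`) produces Gaussian
bumps of controlled relative heights: it validates the peak classifier
and EI arithmetic exactly, but says nothing about network dynamics.
The network simulations themselves are the "real-data" surrogate: they
emulate the circuit's wiring, cell phenotypes and depletion/lesion
operators, but not biological heterogeneity (identical cells within a
population up to initial conditions), conduction delays, synaptic
plasticity, or stochastic channel noise. Passing tests therefore
certify the stated model contracts, not quantitative agreement with
any experimental recording.

# Known limitations

* The cell- and synapse-level constants stand in for an unavailable
  supplementary table; quantitative figure-level reproduction is out of
  scope, and the band-based thalamic-rate threshold reproduces only
  marginally at desk scale.
* Dopamine acts only through the two striatal conductance classes; no
  receptor pharmacology.
* The literal AC-field model cannot produce amplitude-driven spiking
  transitions (see above); the forcing-current trend is reproduced.
* Calcium is a single pooled variable per compartment; Ca currents use
  an ohmic approximation (E_Ca = 100 mV) rather than GHK.
* One detailed MSN per pathway: striatal convergence is represented by
  strong weights, not population averaging.
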