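---
title: "From point-neuron networks to local field potentials: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From point-neuron networks to local field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Point-neuron network models produce spikes, membrane potentials and synaptic
currents, but no extracellular signal: a leaky integrate-and-fire (LIF)
neuron has no spatial extent, so there is no way to place an electrode near
it. `lfpproxy` implements a hybrid scheme for bridging that gap. It (i)
simulates a recurrent LIF network, (ii) replays the identical synaptic event
streams into a population of passive multicompartment neuron models arranged
in a simplified cortical column, (iii) computes a biophysical ground-truth
LFP from the transmembrane currents via the line-source approximation, and
(iv) asks which time series computable from the LIF network alone — firing
rate, mean membrane potential, summed AMPA or GABA currents, or weighted
combinations of the currents — best reproduces that LFP. The headline
product is the *reference weighted sum* (RWS) proxy,

$$\mathrm{LFP}_{\mathrm{RWS}}(t) \propto
\mathrm{Norm}\!\left[\textstyle\sum_{\mathrm{pyr}}\mathrm{AMPA}(t-6\,\mathrm{ms})
- 1.65 \sum_{\mathrm{pyr}}\mathrm{GABA}(t)\right],$$

a fixed-parameter recipe that needs no access to the morphological model at
all.

This vignette records the models, the parameters that matter, the numerical
choices, and the design decisions taken where the problem was genuinely
open — the information a maintainer needs to trust or change the code.

## The point-network stage

The network holds 4000 excitatory and 1000 inhibitory LIF neurons (defaults;
all sizes are configurable) connected randomly with directed probability
0.2, without self-connections. Subthreshold dynamics are
$\tau_m \dot V = -V + \sum \mathrm{PSC}(t)$ on a rest-referenced scale
(rest = 0, threshold 18 mV, reset 11 mV, absolute refractoriness 2 ms for
excitatory and 1 ms for inhibitory cells; $\tau_m$ = 20/10 ms). Each synapse
class follows a bi-exponential filter driven by delta pulses
($\tau_d \dot P = -P + x$, $\tau_r \dot x = -x + \tau_m J \sum_k
\delta(t - t_k - \tau_l)$), with the conduction latency $\tau_l$ = 1 ms on
recurrent connections. The $\tau_m$ prefactor makes postsynaptic currents
carry millivolt units, so the printed synaptic strengths (`lif_synapse_defaults()`)
are the voltage weights.

Two external drives act on every neuron: a thalamic Poisson train at a
constant rate (1.5 spikes/ms in the reference state, swept 0.5–6 for
state-dependence analyses) and a slow "ongoing cortical activity" drive
derived from an Ornstein–Uhlenbeck (OU) process with $\tau_n$ = 16 ms and a
0.25 mV stationary standard deviation.

**OU coupling (open design point).** The source material specifies the OU
amplitude in millivolts but activates the drive through synapses, leaving
the conversion implicit. Our default realises it as a rate-modulated Poisson
train through the cortico-cortical AMPA synapse with rate
$\nu(t) = \nu_0 + \mathrm{OU}(t)/(\tau_m J_{cc})$ of the excitatory
population: quasi-statically, a rate offset $\delta\nu$ moves the mean
membrane potential by $\tau_m J_{cc}\,\delta\nu$, so the voltage-equivalent
fluctuation has exactly the stated 0.25 mV standard deviation for excitatory
cells (0.21 mV for inhibitory cells, whose $\tau_m J_{cc}$ differs — logged,
not hidden). The baseline $\nu_0$ defaults to the rate whose voltage
equivalent is $3\sigma$, making clipping of negative rates rare; negative
instantaneous rates are clipped at zero. A `drive_mode = "current"`
alternative injects the OU value directly into the membrane equation.

**Integration.** The subthreshold system (membrane plus the four synapse
filters per neuron) is linear, so we advance it with the exact
matrix-exponential propagator per 0.05 ms step rather than forward Euler:
subthreshold trajectories then carry no discretisation error and interspike
intervals of driven neurons match the closed form
$\tau_{ref} + \tau_m \ln\frac{\Delta V_\infty - V_{reset}}{\Delta V_\infty - V_{thr}}$
to within one time step (this is a unit test). Spikes are registered at the
end of the step in which the threshold is crossed, without within-step
interpolation; the membrane is clamped at the reset value for the refractory
period while the synaptic filters keep evolving. The first 100 ms of every
run are discarded from analyses.

## Morphologies

The forward model lives in two stacked cylinders (radius and height 250 um).
The lower cylinder, spanning depths $[-250, 0]$ um, contains every soma
(uniformly distributed); the upper cylinder is the lower one shifted up by
the `cylinder_distance` parameter. At the reference separation of 250 um the
cylinders are juxtaposed (a layer-2/3-like arrangement) and $z = 0$ marks
their junction; at separation 0 they coincide, which is the stellate
(closed-field) arrangement; larger separations morph the cells toward
deep-layer pyramidal shapes.

Dendrites are grown toward virtual target axons: 160 straight axons per
layer, laid down as random chords of the cylinder cross-section at random
depths. A cell connects to every axon passing within 150 um of its soma in
the horizontal plane, taking the chord point of closest approach as the
synaptic target; this is our reading of the "reach" rule — it selects
*which* axons a cell contacts, while the tree that wires the selected
targets may span any vertical distance (a deep soma must be able to send an
apical trunk across to the upper cylinder). Growth is the greedy
minimum-spanning-tree construction with a balancing factor: each target is
attached at the tree node minimising
*wiring distance + bf × resulting path length to the soma* (bf = 0.7 by
default), the classic compromise between total cable and conduction time.
Pyramidal cells attach upper-layer targets first and lower-layer targets
second, which produces distinct apical and basal trees; stellate cells use
lower-layer targets only. Virtual axons are discarded after growth and
contribute no membrane. With bf = 0 and unrestricted reach the construction
is exactly Prim's algorithm, which we verify against an independent
minimum-spanning-tree oracle.

**Taper and calibration.** The exact growth-toolbox constants behind the
original morphologies are not published, so diameters follow a centripetal
rule $d = s\,(d_{min} + k\sqrt{\ell_{tip}})$ ($\ell_{tip}$ = longest
downstream path), and the per-cell-type scale $s$ was frozen once by
root-finding so that the population-mean somatic input resistance matches
the quoted values — about 200 MΩ for pyramidal and 175 MΩ for stellate cells
under the morphology-calibration passive set ($R_m$ = 20/10 kΩ cm²,
$R_a$ = 150 Ω cm). `calibrate_taper()` reproduces that procedure. Input
resistance falls monotonically with the diameter scale (more membrane and
less axial shielding), so the root is unique.

Two passive parameter sets circulate in the source material (the
forward-model table prints $R_m$ = 30/20 kΩ cm²; the morphology-calibration
text prints 20/10 with the 200/175 MΩ input resistances). Both are exposed
via `passive_defaults()`; forward simulations default to the table set, and
the input-resistance calibration uses the calibration set, matching the
context each was printed in.

**Ball-and-stick fixture.** For fast end-to-end runs a soma plus one basal
and one apical unbranched cable stands in for a grown cell. Its default
proportions are not free: they are calibrated to three measured statistics
of the grown pyramidal population — the membrane split across the cylinder
junction (≈45% above), the soma's share of membrane (≈9%) and the
soma-to-apical-tip electrotonic distance at 100 Hz (≈2 length constants).
This matters: an electrotonically compact stand-in (thick sticks) suppresses
the dipole of homogeneously distributed AMPA synapses and grossly distorts
the AMPA/GABA balance of the resulting LFP. The calibrated defaults are
0.55 um sticks, a 130 um basal cable, an apical cable reaching the top of
the upper cylinder, and a 5 um soma.

## The forward model

Compartmentalisation follows the electrotonic rule: every compartment is
shorter than the length constant at 100 Hz,
$\lambda_f = \lambda_{DC}\big/\sqrt{\tfrac12\,(1 + \sqrt{1 + (2\pi f R_m C_m)^2})}$,
with an optional hard cap for finer spatial resolution. The soma becomes a
cylinder of length equal to its diameter (sphere-matched lateral area), and
a dendrite leaving the soma keeps its own calibre rather than inheriting the
soma radius.

Synapses are placed one per presynaptic partner, on compartments drawn with
probability proportional to membrane area within the depth region permitted
by the distribution mode: `REF` (GABA restricted to the lower cylinder, AMPA
everywhere — the reference arrangement), `HOM`, `AM_UP`, `AM_DOWN` and
`AMR_UP` reproduce the alternative-distribution analyses. Synaptic waveforms
are the same bi-exponentials as in the point network, peak-normalised so an
isolated event reaches exactly the tabulated weight (nA in current mode, uS
with reversal potentials in conductance mode). No latency is applied at this
stage — the point network already shifted recurrent spike times — and the
external Poisson trains are replayed verbatim, so each multicompartment
neuron receives synaptic input identical to its point-neuron counterpart.
Every pyramidal point neuron has a forward counterpart; this matters because
the thalamic trains are independent across neurons, and a partial forward
population would decorrelate that input component between the proxy traces
and the ground truth.

The passive cable system is advanced by backward Euler (unconditionally
stable for this dissipative linear system; Crank–Nicolson adds accuracy but
not robustness, and a convergence test shows halving the 0.1 ms step changes
somatic voltages by well under 1%). In current mode the system matrix is
constant and block-diagonal across the mutually uncoupled cells, so its
sparse inverse is precomputed and each step costs one matrix–vector product.
Per-compartment transmembrane currents (capacitive + leak + synaptic) are
recovered from the axial currents, $I_i = -(\mathbf{L}v)_i$, which makes
per-cell current conservation hold to machine precision at every step — the
property the dipolar structure of the LFP rests on, and the first thing the
test suite asserts. One consequence of current-based synapses worth knowing:
nothing pins the membrane potential, so a tonically driven passive cell
integrates to a large depolarised offset. That offset is physically
irrelevant here — the dynamics are linear and only transmembrane *currents*
enter the LFP — and matches the source framework's own observation that the
multicompartment somatic potentials do not track the point-neuron ones.

Extracellular potentials use the line-source approximation in an infinite
homogeneous resistive medium ($\sigma$ = 0.3 S/m): each compartment is a
uniform line current and its potential is the analytic integral of the
point-source kernel, evaluated in the numerically robust inverse-hyperbolic
form and checked against direct quadrature in the tests. For electrodes near
a segment the perpendicular distance is clamped to the segment radius
(standard practice; the source is silent). Electrodes are ideal points; the
default laminar array spans depths −400 to +400 um. The printed electrode
count (32) and the printed range/step (25 um over ±400) disagree by one; we
follow the range/step, giving 33 positions, which contains the ±100 um
reference depths either way. The depth-resolved current dipole moment is
$d_z(t) = \sum_i z_i I_i(t)$, summarised by its standard deviation over
time. The ground-truth LFP used for proxy scoring sums pyramidal
contributions only: stellate cells are closed-field and contribute
negligibly (a property test pins their population dipole at far below the
pyramidal one).

## Proxies and scoring

All proxies are z-scored (population-variance convention) so that only the
temporal shape is compared; the spatial amplitude is a per-electrode scale
fitted by least squares. Simple proxies: firing rate, mean membrane
potential, summed AMPA (positive), summed GABA (negative), the signed sum
$\sum I$ (partial cancellation) and the sum of absolute values
$\sum|I| = \mathrm{AMPA} - \mathrm{GABA}$. The weighted sum
$\mathrm{WS}(\alpha, \tau_A, \tau_G)$ generalises these (α = 1/−1 with equal
delays recovers $\sum|I|$/$\sum I$ bit-for-bit — a unit test), and the RWS
fixes α = 1.65, $\tau_A$ = 6 ms, $\tau_G$ = 0. Delays are integer-bin shifts
with trimmed (never padded) edges, avoiding spurious boundary correlation.

Per electrode, simple proxies get a cross-correlation delay search (the lag
of the peak absolute correlation, sign retained — it flips across the
inversion point) followed by scale/offset fitting; WS is fitted by
exhaustive search over $\tau_A \in [0, 10]$ ms and $\tau_G \in [-2, 2]$ ms
in 0.5 ms steps (covering the published optima with margin; the original
grid is unstated) with per-gridpoint ordinary least squares on the two
shifted regressors, $\alpha = -b_G/b_A$. Model comparison uses
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + K\ln n$ with K = 2 for simple proxies
(scale, delay) and K = 4 for the WS family, on a common analysis window.
Summary statistics are unweighted means over all depths; no near-inversion
band is excluded by default (configurable downstream, since the fit is
meaningless where the LFP itself vanishes). Spectra use an averaged modified
periodogram (1 s Hann segments, 50% overlap; the original estimator is
unstated), with the gamma summary taken as the 30–100 Hz peak.

## Reduced study conditions and what they show

The full reference configuration (4000 + 1000 neurons, 10.1 s, grown
morphologies) is reproducible with this package but takes hours on one CPU.
The routine checks therefore run a scaled configuration
(`scaled_config()`): 400 + 100 LIF neurons, 3 s after warm-up, and
ball-and-stick forward counterparts for all 400 pyramidal cells (roughly
2000 compartments at the 150 um cap, 0.1 ms forward step). Problem sizes in
the test suite (20 grown cells per type for the input-resistance check,
20 s OU traces, and so on) were chosen once as the smallest sizes at which
the tested statistics are stable.

Scaling keeps per-synapse weights fixed while cutting partner counts
tenfold, so the scaled network sits in a more mean-driven, less
inhibition-dominated regime (excitatory rates near 17 Hz rather than a few
Hz). Consequences we observe and do not paper over: the GABA-only proxy
edges out $\sum|I|$ (the full-scale ordering has them reversed by a similarly
small margin), the fitted α comes out near 2.7 rather than 1.65 (more of the
LFP variance loads on GABA), and the $\sum|I|$ cross-correlation lag at the
±100 um depths is near 2 ms rather than 1 ms. The fitted AMPA delay
(≈7 ms), the RWS's advantage over every simple proxy, the BIC preference for
the WS family, the depth profile with its inversion point near the cylinder
junction, and the closed-field suppression of the stellate dipole all
reproduce at the reduced scale. Passing the scaled checks therefore
demonstrates the machinery and the qualitative physics, not the exact
full-scale coefficients; and none of it says anything about biological
recordings, where media are inhomogeneous, synapses are plastic and NMDA
currents exist — all outside this model by construction.

## Degenerate inputs and edge handling

Zero-variance traces are rejected rather than silently normalised; a
weighted-sum fit with collinear or absent regressors (e.g. GABA identically
zero) warns and reports an unidentifiable α as `NA`. Unreachable growth
targets are dropped with a warning, down to a degenerate single-node tree.
Zero-length line sources fall back to the point-source formula. Synapse
placement fails loudly when a distribution mode permits no compartment for
a class (e.g. `AM_UP` on a cell confined to the lower cylinder). The cable
solver aborts on voltages outside a generous bound (10 V in current mode,
where DC offsets are legitimate; the reversal-potential range in
conductance mode).

## Known limitations

No NMDA synapses, plasticity, heterogeneous weights, active conductances or
spiking in the forward stage; no inhomogeneous or frequency-dependent
extracellular media; single-column geometry only. The conductance-based
forward mode refactorises the system each step and is intended for small
models. Reconstructed real morphologies are not bundled; the growth
algorithm plus the SWC reader cover that use case.
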