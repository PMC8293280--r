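---
title: "Modelling A-type potassium control of dopaminergic pacemaking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling A-type potassium control of dopaminergic pacemaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kv4pace)
```

## The scientific problem

Substantia nigra pars compacta (SNc) dopaminergic neurons fire
spontaneously and regularly ("pacemaking") and respond to the end of a
hyperpolarizing input with a characteristically delayed rebound spike.
Both behaviors are shaped by the transient A-type potassium current
(I~A~, carried by Kv4 channels) and its functional counterpart, the
hyperpolarization-activated cation current (I~H~). `kv4pace` implements
the computational machinery needed to study how the biophysical
parameters of these two currents — maximal conductances, voltage
dependence, inactivation kinetics — control the interspike interval
(ISI) and the postinhibitory rebound delay: a multicompartment
conductance-based neuron model, a parameter-database sweep with
dimensional stacking, current- and voltage-clamp feature extraction, the
associated statistical procedures, and synthetic-data generators that
stand in for patch-clamp recordings and reconstructed morphologies.

## The conductance-based model

Each compartment obeys the membrane equation

$$C_m \frac{dV}{dt} = -\sum_i g_i\,(V - E_{rev,i}) - I_{axial},$$

with six active conductances: fast sodium (I~Na~), delayed rectifier
(I~KDR~), A-type potassium (I~A~), HCN (I~H~), L-type calcium (I~CaL~)
and SK calcium-activated potassium (I~SK~), plus an ohmic leak. Gating
follows Hodgkin–Huxley kinetics,
$I = \bar g\, m^a h^b (V - E_{rev})$, with Boltzmann steady states
$m_\infty(V) = 1/(1+\exp[-(V-V_{50})/k])$ and first-order relaxation
$\dot m = (m_\infty - m)/\tau_m$. Every constant — $V_{50}$, $k$, gate
exponents, the closed-form $\tau(V)$ rules, reversal potentials and
region-specific densities — lives in one unit-annotated configuration
file (`inst/extdata/channels.yaml`, read by `channel_defaults()`), so a
single edit corrects any value. Two couplings are built in:

* **I~A~ kinetics**: activation is 50× faster than inactivation
  ($\tau_m = \tau_h / 50$) and the activation $V_{50}$ sits 50 mV above
  the inactivation $V_{50}$; both kinetics are voltage-independent.
* **I~A~/I~H~ voltage dependence**: the A-current half-inactivation
  voltage co-varies with the HCN activation $V_{50}$ as
  $V_{50,\mathrm{inact}}^{A} = 0.814\,V_{50,\mathrm{act}}^{H} + 3.36$,
  mirroring the correlation measured in these neurons. Over the HCN grid
  ($-100$ to $-80$ mV) this induces the documented $-78$ to $-62$ mV
  inactivation range.

The SK current is calcium- rather than voltage-gated:
$O_\infty = \mathrm{Ca}_i^4 / (\mathrm{Ca}_i^4 + K^4)$ with
$K = 1.9\times10^{-4}$ mM.

Channel placement follows the region rule: soma, dendrites and the
axon-start section carry all six currents; the axon initial segment
(AIS) and distal axon carry only Na and KDR, at elevated densities
(4000/4000 and 400/400 pS/µm²) so that action potentials initiate in the
AIS — a property the package tests assert rather than assume.

### Calcium dynamics — a deliberately re-derived operating point

Only the decay-model *form* of the calcium mechanism is constrained:
influx proportional to I~CaL~ into a submembrane shell, first-order
return to baseline. Its constants are free parameters, and they matter:
with raw Faraday-scaled influx into a 0.1 µm shell, subthreshold calcium
settles an order of magnitude above the SK half-activation, SK turns
into a tonic potassium clamp and the model rests near −65 mV instead of
firing. We therefore include a rapid-buffering factor — only a fraction
(default 0.025, i.e. an endogenous buffer capacity near 40, a standard
textbook value for neuronal cytoplasm) of the entering calcium stays
free — with a 0.1 µm shell, 5 ms decay and $10^{-4}$ mM baseline. At
this operating point SK activates phasically after each spike
(afterhyperpolarization) and deactivates between spikes, and the default
model paces regularly at 3–10 Hz across the biophysical grid. All four
constants are exposed in `calcium_model()`.

## Numerics

The cable equation is advanced by a **backward-Euler step with Hines
elimination**: ionic conductances are frozen at the step's gate values,
making the membrane current linear in $V$; the resulting symmetric
tree-structured linear system is solved exactly in $O(n)$ by eliminating
from the leaves to the root (compartments are topologically ordered so
parents precede children). Gates then relax by the *exact* exponential
update $m' = m_\infty + (m - m_\infty)e^{-dt/\tau}$ at the new voltage
(first-order staggered scheme), and shell calcium integrates its linear
ODE exactly over the step. The scheme is unconditionally stable at the
default $dt = 0.02$ ms; halving $dt$ changes the post-stabilization ISI
by well under 1%. Steady states and relaxation factors are evaluated
through 0.05 mV lookup tables with linear interpolation inside the C++
inner loop; the interpolation error ($<10^{-4}$ in the gate variables)
is far below the discretization error of any reported feature. A guard
aborts with the failing step if $|V|$ exceeds 200 mV.

Spatial discretization follows the d_lambda rule: each section is split
into the smallest odd number of compartments no longer than
$0.1\,\lambda_{100}$, where
$\lambda_f = 10^5 \cdot \tfrac12\sqrt{d/(\pi f R_a C_m)}$ µm is the AC
length constant at 100 Hz. Neither the fraction nor the frequency is
stated by the source modelling convention beyond its simulator default,
so 0.1 and 100 Hz are adopted and configurable
(`discretization_policy()`). Odd counts give every section a true
midpoint compartment, which is where recordings are taken. Compartment
areas sum exactly to the section's cylinder area; the soma is a cylinder
of length equal to its diameter (area $\pi d^2$, equal to the sphere of
the same diameter).

## Protocols

* **Pacemaking** (`run_pacemaking()`): 8000 ms at $dt = 0.02$ ms from
  −70 mV with no injected current; the first four spikes are excluded
  while the rhythm stabilizes. Runs with fewer than six spikes are
  flagged non-pacemaking, never dropped.
* **Rebound** (`calibrate_hyperpolarizing_amplitude()`,
  `run_rebound()`): a 1 s somatic current pulse whose amplitude is
  bisected until the peak hyperpolarization reaches −120 ± 2 mV —
  re-calibrated per morphology *and* per grid point — followed by the
  delay from pulse offset to the first rebound AP peak. Measuring to the
  AP peak (not threshold crossing) makes the delay insensitive to the
  detection criterion; the criterion itself (dV/dt crossing 10 mV/ms,
  2 ms refractory) is explicit configuration.

## Feature extraction

Current-clamp: spike times (AP peaks), mean ISI and its coefficient of
variation (CV = SD/mean, **sample** SD with $n-1$ — the convention the
worked reference values use), AP threshold / amplitude / half-width /
AHP trough and latency / rise and decay slopes, sag amplitude (peak
hyperpolarization minus the mean over the last 10% of the pulse), and
excitability measures: start frequency $=1/\mathrm{ISI}_1$, end
frequency $=1/\overline{\mathrm{ISI}_{last2}}$, gains as least-squares
slopes versus step amplitude per 100 pA, and the spike-frequency
adaptation index start/end at the largest common step. The gain/SFA
formulas come from the upstream literature rather than a restated
definition, so they are documented here as the package's fixed
interpretation and are configurable in code.

Voltage-clamp: the A-current is isolated by the two-prestep subtraction
(−100 mV de-inactivated minus −40 mV inactivated, then the residual
−40 mV baseline removed, which cancels linear leak exactly); its
inactivation curve is a least-squares Boltzmann fit of peak current
versus prestep voltage, its decay a mono-exponential
$A e^{-t/\tau} + C$ fit (a residual RMS above 2% of the amplitude flags
non-mono-exponential input), and its charge the trapezoidal integral
over the 500 ms step. HCN features use the steady-minus-instantaneous
current convention with a Boltzmann fit of normalized chord conductance;
the delayed-rectifier I–V reports per-step peak and late mean.

## The model database and dimensional stacking

The four swept parameters are `g_A` (15–150 pS/µm²), `tau_h_A`
(15–150 ms), `g_H` (0.25–2.5 pS/µm²) and `v50_h_act` (−100 to −80 mV),
each at five linearly spaced values including the endpoints
("equidistributed" is read as linear; a log switch exists). The full
design is $5^4 = 625$ combinations × 22 morphologies = 13,750 models;
`run_sweep()` assembles each morphology once and re-parameterizes it per
grid point, records mean ISI and calibrated rebound delay per model,
flags silent or censored runs, and is deterministic and independent of
execution order. `average_by_combination()` marginalizes over
morphologies (625 rows); `dimensional_stack()` embeds the 4-D grid into
a 25×25 heatmap (outer axes g_A × v50, inner axes tau × g_H, log10
transform) through an index bijection that tests verify losslessly.

At desk scale the package uses a **reduced design**
(`reduced_sweep_points()`): the 16 grid corners, which span the
parameter space for the standardized sensitivity regression, plus each
parameter's min/central/max at central other values, which expose the
marginal trends the full database shows — ISI and rebound delay
increase with g_A, rebound delay decreases with g_H. Two stylized
morphologies × 25 grid points (50 8-second simulations, about two
minutes of CPU) are enough for these qualitative conclusions; the
13,750-run database and the full heatmaps are out of desk scope by
design.

## Statistics

The analysis chain mirrors standard ephys practice: positive skewed
variables are log-transformed and z-scored (`log_standardize()`);
pairwise association uses Pearson's *r* when a Shapiro–Wilk test on the
linear-regression residuals is compatible with normality (p ≥ 0.05) and
Spearman's ρ otherwise, with Benjamini–Hochberg FDR control across each
comparison family. Multiple regression proceeds by exhaustive best-subset
search per model size (adjusted R², AIC, BIC reported), final selection
by minimum mean RMSE over a repeated (20×) 10-fold cross-validation with
seeded fold shuffling, and a VIF < 1.5 collinearity screen
(VIF$_j = 1/(1-R_j^2)$). The Fisher exact test is two-sided by the
summation convention — the sum of hypergeometric probabilities of all
tables no more probable than the observed one — which an exhaustive
enumeration oracle pins down in the tests. `sensitivity_regression()`
reports full-model standardized coefficients, used both for the model
database (predictors g_A, tau, g_H, v50 against log ISI or log rebound
delay) and for per-neuron data.

## Synthetic data: what it emulates, and what it does not

`sample_population()` draws per-neuron biophysics from a Gaussian copula
with log-normal marginals for the positive skewed quantities (medians
and IQRs set to the reported wild-type or Kv4.3-knockout values, e.g.
WT ISI 669.5 ms, I~A~ tau 30.9 ms, I~H~ amplitude 453 pA) and normal
marginals for the two $V_{50}$s (e.g. −68.91 ± 5.10 mV). The latent
correlation couples the two voltage dependences (0.658, the reported
coefficient) and log I~A~ tau with log I~H~ amplitude (−0.4 by default —
the sign is reported, the magnitude is not, so it is configuration, not
ground truth). ISI and rebound delay derive from the standardized latent
biophysics through a configurable linear model (defaults: positive tau
coefficient, negative I~H~-amplitude coefficient, plus a $V_{50}$ term
for rebound delay, echoing the reported predictor sets) with Gaussian
noise completing the variance to 1 so the marginal scale targets are
met; medians are matched exactly in expectation, IQRs approximately.
Every generator returns a truth record sufficient to score downstream
recovery, and a zero-noise draw closes the loop: refitting returns the
generative coefficients to machine precision.

What the generators do **not** emulate: patch-clamp artifacts (series
resistance, capacitive transients, junction potentials), bursting or
irregular firing, morphological reconstruction error, or any causal
biophysics linking the sampled parameters to the sampled features — the
feature model is linear by construction. Passing recovery tests on these
synthetic populations therefore validates the *statistical machinery*,
not the biological claims; conversely, the simulator-side tests validate
the *mechanistic* claims on stylized rather than reconstructed
morphologies.

## Numerical and design choices, collected

* Outward-positive current convention everywhere; gate exponent 0
  encodes "no such gate".
* The partially garbled source table is adopted under one documented
  parse (see `channels.yaml`); the two ambiguous maximal conductances
  (I~CaL~ 1, I~SK~ 0.125 pS/µm²) are flagged there.
* The HCN time-constant formula is implemented exactly as printed
  (Gaussian in $V$ with no offset, peak 1656 ms at 0 mV), although its
  maximum at 0 mV is physiologically odd; it only matters far from the
  subthreshold range where I~H~ operates.
* The L-type $\tau_m(V)$ has a removable singularity at −39.26 mV,
  handled with `expm1`.
* Boltzmann and exponential fits use Levenberg–Marquardt
  (`minpack.lm`); starting values come from log-linear or quantile
  heuristics and the routines warn (rather than fail) on saturated or
  non-mono-exponential input.
* Fold assignment, population draws and morphology generation all flow
  from explicit integer seeds; repeated calls are bitwise identical.

## Known limitations

Stylized morphologies are statistical stand-ins, not reconstructions;
absolute ISIs differ from the biological medians even though every
qualitative trend (g_A slows pacemaking and delays rebound, g_H opposes
it, AIS initiation, sag scaling with g_H) is reproduced. Temperature
dependence, stochastic gating, synaptic input and voltage-clamp
simulation of the full model are out of scope; synthetic voltage-clamp
traces are generated analytically instead. The excitability definitions
and the I~H~ two-step protocol follow documented interpretations of
upstream conventions and are not asserted against the reported
population tables.
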