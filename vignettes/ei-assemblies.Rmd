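---
title: "Homeostatic formation of E/I assemblies: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic formation of E/I assemblies: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`eiassembly` simulates a recurrent rate network of $N_E$ pyramidal (Pyr)
neurons and $N_I$ parvalbumin-expressing (PV) interneurons. Activations
follow Wilson–Cowan dynamics

$$\tau_E \dot h^E = -h^E + W^{E\leftarrow E} r^E - W^{E\leftarrow I} r^I
  + I_{bg} + I(s), \qquad
  \tau_I \dot h^I = -h^I + W^{I\leftarrow E} r^E - W^{I\leftarrow I} r^I
  + I_{bg},$$

with rectified rates $r = [h]_+$. Weight matrices store magnitudes; the
inhibitory sign lives in the dynamics. Each Pyr neuron receives external
input tuned to a three-dimensional periodic stimulus space (orientation,
temporal and spatial frequency, each in $[-\pi, \pi)$), modelled as a
separable product of von Mises factors
$I_i(s) = I_{max}\prod_d \exp\{\kappa(\cos(s_d - \phi_{i,d}) - 1)\}$ with
$\kappa = 1$ and $I_{max} = 50$ Hz. The von Mises form is the simplest
bell-shaped periodic tuning with the stated width and peak; because the
exponent is additive across dimensions, a product of one-dimensional
factors and a single three-dimensional exponential coincide. PV neurons
receive only untuned background input, so any stimulus selectivity they
acquire must come from the recurrent circuitry — this is the scientific
point of the model.

Stimuli live on an evenly spaced $n \times n \times n$ grid ($n = 12$ at
full scale, 1728 stimuli). Grid points sit at $-\pi + k\,2\pi/n$: the
half-open convention includes $-\pi$ and excludes $\pi$; on a periodic
domain the choice is immaterial because all quantities are translation
invariant. Pyr preferences tile the space evenly: when $N_E$ equals the
number of grid stimuli they coincide with the grid; otherwise $N_E$ must
be a perfect cube $m^3$ and the preferences form their own even lattice
(the full-scale network has $N_E = 512 = 8^3$ under the $12^3$ stimulus
grid).

Pyr–Pyr weights are structural, not plastic: $W^{E\leftarrow E}_{ij} =
[\mathrm{corr}(I_i, I_j) - C]_+$, with the crop threshold $C$ chosen so
the connection density matches $p = 0.6$, the diagonal forced to zero and
rows rescaled to the total $J^{E\leftarrow E} = 2$. The remaining
projections are Bernoulli($p$) masks with log-normal weights (log-sd
$\sigma = 0.65$; the log-normal location is irrelevant because each row
is rescaled to its prescribed total $J$). Connectivity is drawn once and
never changes: plasticity only rescales existing synapses. Self
connections are excluded in $W^{E\leftarrow E}$ (a neuron's correlation
with itself is 1 and would dominate the cropping) and in
$W^{I\leftarrow I}$ by the same convention.

## Plasticity

Both plastic projections — the PV input synapses $W^{I\leftarrow E}$ and
the PV output synapses $W^{E\leftarrow I}$ — descend a single homeostatic
objective, the mean squared deviation of Pyr activations from a target
rate $\rho_0 = 1$ Hz across stimuli. The output rule is
$\Delta W^{E\leftarrow I}_{ji} \propto (h^E_j - \rho_0)\, r^I_i$: Hebbian
in the presynaptic interneuron rate and the signed postsynaptic
deviation. The local input rule is $\Delta W^{I\leftarrow E}_{ij} \propto
[\sum_k W^{I\leftarrow E}_{ik}(r^E_k - \rho_0)]\, r^E_j$; because input
rows are multiplicatively renormalised to $J^{I\leftarrow E} = 5$ after
every update, the bracket is the deviation of the interneuron's recurrent
excitatory current from the target $I_0 = J^{I\leftarrow E}\rho_0$, which
makes the rule local. The rules are implemented exactly as stated: the
output rule reads activations $h^E$, the local input rule rates $r^E$.

The gradient-based variant replaces the local input-rule error by the
error propagated through the transposed output weights,
$[\sum_k W^{E\leftarrow I}_{ki}(h^E_k - \rho_0)]\,g_i$, with the
rectifier gate $g_i = \mathbf{1}[h^I_i > 0]$ required for a true
derivative; the gate is omitted in the local rule, which is written
without one. Higher-order recurrent interactions are neglected in both
(the first-order, steady-state form); the unit tests verify the gradient
rule against central finite differences of exactly this truncated
objective on toy networks. Over training, the local input updates align
with the gradient-based ones — feedback alignment — because balancing
excitation with feedback inhibition favours symmetric Pyr–PV coupling.
The recorded alignment angle compares the error-driven parts of the two
updates; the weight-decay term is excluded from the comparison since it
is identical in both rules and would trivially shrink the angle.

Both weights carry a weak decay $-\delta W$ ($\delta = 0.1$), entering
the raw update with the same learning-rate scaling as the main term; it
removes the redundancy that a rescaling of input synapses can be
compensated by output synapses. Sign constraints use an exponential
reparameterisation $w = e^u$: raw updates are chain-ruled into parameter
space ($\Delta u = \eta\,\Delta w \cdot w$), making weight changes
multiplicative and positivity exact. Two alternatives are provided for
comparison: `reparam = "eg"` (exponentiated gradient, $\Delta u =
\eta\,\Delta w$, which removes the extra factor $w$ that makes large
weights move disproportionately faster) and `reparam = "clip"`
(additive updates clamped at zero). Note a consequence of the default:
because the log-weight velocity scales with $w$ itself, normalised rows
are driven towards strongly bimodal weight distributions — a small
co-tuned ensemble of strong synapses per interneuron, with the rest
decaying far below any detection threshold. At full scale each
interneuron's surviving ensemble still contains many synapses; in the
reduced preset below, where the stimulus grid is four times coarser and
each interneuron samples only a few dozen pyramidal cells, the surviving
ensemble can shrink to a handful of synapses, which limits how many
detectable reciprocal pairs remain for the sampling analyses. The gradient variant is
optimised with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-9}$) in parameter space. Updates are applied once per
stimulus presentation from the steady state, output and input matrices
in that order, then input rows are renormalised (in both rule variants).

## Numerical choices

The steady state for each stimulus is found by forward Euler integration
($dt = 1$ ms) until the per-step activation change falls below
$10^{-6}$ Hz, with two accelerations that do not change the fixed point:
warm starts from the previous stimulus, and an exact algebraic solve of
the piecewise-linear fixed point once the active set (the sign pattern of
$h$) has been stable for 50 consecutive steps, accepted only when the
solution's sign pattern is self-consistent.

Two pathologies require care. First, forward Euler at $dt = 1$ ms can be
linearly unstable for strongly underdamped E–I modes even when the
continuous fixed point is stable; the solver then retries the exact solve
with the time-averaged sign pattern and, failing that, halves the
internal step (down to $dt/16$) — the fixed point is independent of the
step size. Second, some weight configurations traversed during learning
have no stable fixed point at all: the dynamics settle into a bounded
limit cycle. Training and measurement then use the cycle-averaged
activations and rates (`on_cycle = "average"`; rates are averaged
separately from activations because rectification is nonlinear), which is
the natural substrate for homeostatic rules driven by average activity. A
bounded oscillation is declared after 0.8 s of simulated time without
convergence (about sixteen excitatory time constants, several oscillation
periods), and only if the amplitude is stationary; growing amplitudes
are reported as numerical divergence. The strict error contract
(`on_cycle = "error"`) remains the default of `steady_state()` itself.

Degenerate-input conventions: the stimulus selectivity (response
skewness, population moments) of a constant response is defined as 0 — a
constant response is maximally unselective; response similarity and
update angles are errors, not silent zeros, for all-zero inputs; empty
influence bins are reported missing rather than zero.

## Problem sizes and the reduced preset

The full-scale protocol (512 Pyr, 64 PV, $12^3$ stimuli, 500 trials,
$\eta = 10^{-5}$) takes hours on one CPU. The package therefore defines a
reduced preset used by the test suite and the worked examples: 64 Pyr
tiling a $4^3$ grid, 8 PV, 100 trials — the same Pyr-to-PV ratio and even
coverage invariant. The local learning rate of the preset is
$\eta = 1.2 \times 10^{-5}$, calibrated so that the reduced protocol
reaches the same endpoint the full-scale protocol is run to — pyramidal
rates converged to the homeostatic target. Naive rescaling arguments
(135-fold fewer presentations, eight-fold larger per-synapse weights)
suggest much larger rates, but rates beyond a few times $10^{-5}$
destabilise the reduced network: transiently stripping inhibitory
control tips the $J^{E\leftarrow E} = 2$ excitatory recurrence into
runaway. The preset also reduces the perturbation experiment (30
perturbed neurons, all grid stimuli) and the sampling analysis (1000
resamples).

What the reduced runs do and do not show: they exercise every mechanism —
homeostatic convergence, assembly formation, knock-out contrasts,
feedback alignment, perturbation-induced feature competition — but with 8
interneurons the inhibitory control is coarse, residual deviations from
the target are larger than at full scale, and sampled correlation values
are noisier. Full-scale quantities reported in the literature (e.g. the
mean pairwise receptive-field $R^2$ before learning) are recomputed at
full scale by `scripts/acceptance.R`, which is cheap because it needs no
training.

The synthetic stimulus protocol emulates a dense, balanced sampling of a
periodic feature space with exactly even coverage by the excitatory
population; real visual cortex sees neither an even tiling of preferred
features nor equal stimulus exposure, and real PV cells receive some
tuned feedforward drive. Passing tests therefore validate the mechanism
under idealised conditions, not a quantitative match to any particular
cortex.

## Worked example

```{r, eval = FALSE}
library(eiassembly)

net <- ei_network(network_params(NE = 64, NI = 8, n_per_dim = 4), seed = 1)
cfg <- plasticity_config("local", eta = 1.2e-5)
fit <- ei_train(net, cfg, trials = 100, seed = 2, verbose = TRUE)
summary(fit)

resp <- predict(fit)

# weight/response-similarity correlations over sampled reciprocal pairs
# (sampled before learning here; after learning at this scale only a
# handful of pairs remain above the detection threshold, see above)
set.seed(3)
sm <- sample_reciprocal_pairs(net$W, net$masks, response_tensor(net), n = 100)
sample_correlations(sm)

inf <- perturb_influence(fit, n_perturbed = 30, seed = 4)
bin_influence(inf, rf_correlation_matrix(resp))
```

## Known limitations

* A single interneuron class; no feedforward inhibition, delays,
  conductances or noise.
* The gradient variant implements the steady-state, first-order form of
  the objective's gradient, not backpropagation through the transient
  dynamics.
* Influence bin edges default to 10 equal-width bins over the observed
  receptive-field-correlation range; the binning granularity is a
  presentation choice.
* At the reduced scale, endpoint quantities of training (for example the
  median steady-state activation after 100 trials) vary substantially
  between network realisations: with 8 interneurons a single connectivity
  draw decides how well the homeostatic loop can balance each pyramidal
  cell, and runs from different seeds can straddle the target by several
  tenths of a hertz. Conclusions at this scale should be drawn from
  several seeds.
* The sampling analysis draws reciprocally connected Pyr–PV pairs (the
  input–output correlation requires pairs); detection thresholds are
  absolute ($10^{-4}$, roughly four orders below the strongest synapses),
  with a relative mode available.
* Result stores are RDS files plus YAML configs and CSV/JSON metric
  exports.
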