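# eiassembly

Simulation of a recurrent rate network in which homeostatic synaptic
plasticity of parvalbumin (PV) interneuron input *and* output synapses
builds excitatory–inhibitory (E/I) assemblies: groups of pyramidal (Pyr)
cells and interneurons coupled by strong reciprocal synapses and shared
stimulus preference. The package is for computational neuroscientists who
want to study how stimulus-specific feedback inhibition can develop in
circuits without feature topography, and what it does to interactions
between excitatory neurons.

## The model

Activations follow Wilson–Cowan dynamics with rectified-linear rates
r = [h]₊:

    τ_E dh^E/dt = −h^E + W^{E←E} r^E − W^{E←I} r^I + I_bg + I(s)
    τ_I dh^I/dt = −h^I + W^{I←E} r^E − W^{I←I} r^I + I_bg

Each Pyr neuron receives external input tuned (von Mises, κ = 1, peak
50 Hz) to a point of a periodic 3-D stimulus space (orientation,
temporal and spatial frequency); PV cells receive only untuned
background. Pyr→Pyr weights grow with input signal correlation,
`[corr − C]₊`, cropped so the density is p = 0.6; the other projections
are random log-normal with fixed row totals.

Both plastic projections descend one homeostatic objective,
E = ⟨½ Σ_j (h_j^E − ρ₀)²⟩_s with target ρ₀ = 1 Hz:

    ΔW^{E←I}_{ji} ∝ (h_j^E − ρ₀) r_i^I            (output synapses)
    ΔW^{I←E}_{ij} ∝ (I_i^{E,rec} − I₀) r_j^E      (input synapses, local)

with weight decay, sign-constraint reparameterisation, and
multiplicative row normalisation of the input matrix (I₀ = J^{I←E}ρ₀).
A non-local gradient variant (error propagated through the transposed
output weights, Adam optimiser) is included; the local input rule aligns
with it over learning (feedback alignment, tracked as the angle between
the two update matrices).

Quantitative measures: response similarity (normalised tuning overlap),
stimulus selectivity (response skewness), update angles, sampling of
reciprocally connected Pyr–PV pairs with Pearson significance analysis
and resampling fractions, receptive-field correlation / mean R²,
perturbation influence maps binned by tuning similarity, and a
Mann-Whitney U test.

## Worked example

```r
library(eiassembly)

net <- ei_network(network_params(NE = 64, NI = 8, n_per_dim = 4), seed = 1)
fit <- ei_train(net, plasticity_config("local", eta = 1.2e-5),
                trials = 100, seed = 2)
print(fit)
#> trained E/I network (local rule), 100 trials x 64 stimuli
#> mean |hE - rho0|: 16.989 (first trial) -> 14.794 (last trial)

resp <- predict(fit)                        # steady-state rates, all stimuli
median(resp$activations[1:64, ])            # median Pyr activation (target 1 Hz)
#> [1] 1.3058

inf <- perturb_influence(fit, n_perturbed = 30, seed = 4)
head(bin_influence(inf, rf_correlation_matrix(resp)), 3)
# mean influence of perturbing one Pyr cell on others, by tuning similarity
```

The median steady-state Pyr activation moves from −1.13 Hz (before
learning, most cells suppressed or silent for most stimuli) towards the
homeostatic target of 1 Hz; the influence table shows whether similarly
tuned neurons amplify (positive) or suppress (negative) each other after
a single-cell perturbation. `reproduce("fig1" | "fig2" | "fig3" | "fig4",
scale = "reduced", seed = 1)` drives the four standard experiments
(full plasticity, output knock-out, input knock-out, perturbation
analysis) end to end and returns a self-describing store; a thin CLI over
the same functions is in `inst/scripts/eiassembly-cli.R`.

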