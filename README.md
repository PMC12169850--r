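# replaynet

Recurrent spiking networks whose synapses all follow one predictive
plasticity rule, and whose spontaneous activity learns to replay
stimulus-evoked patterns with the probabilities experienced during
training.

## The problem

Spontaneous cortical activity is not noise: it cycles through activity
patterns resembling stimulus-evoked responses, with frequencies that
track how often those stimuli were experienced — a candidate neural
implementation of a learned prior over sensory events. `replaynet` is a
simulation package for studying how such a prior can be written into
recurrent synaptic structure by purely local, unsupervised learning. It
is aimed at computational neuroscientists who want to reproduce,
perturb, or extend this class of models: self-organizing cell
assemblies, excitation–inhibition balance with plastic inhibition,
homeostatic intrinsic excitability, and perceptual-decision biases read
out from spontaneous activity.

## The model

Networks of `N` Poisson spiking neurons receive `K` Poisson input
trains through an all-to-all afferent matrix `W` and interact through
recurrent matrices. Spikes drive exponentially decaying presynaptic
traces (`tau` = 15 ms); in the mixed-sign variant the membrane
potential is

    u = W x + (M - G) y

with signed `W`, `M` and non-negative inhibitory-only `G`. The
instantaneous rate is a sigmoid of `u` with ceiling `phi0` = 50 Hz and
a homeostatically regulated threshold driven by a slow envelope `h` of
the membrane potential (decay `tau_h` = 10 s); spikes are Bernoulli
events with probability `f * dt / 1000` per 1-ms Euler step.

Every connection class maintains a linear prediction of the neuron's
rate (`v_W = W x`, `v_M = M y`, `v_G = G y`), and every weight update
is the same local rule,

    dw_ij = eta * phi0^-1 * (1 - phi(v_i)/phi0) * (f_i - phi(v_i)) * trace_j,

the prediction error times the presynaptic trace (`eta` = 1e-4; `phi`
is the static sigmoid with midpoint 3 and slope 15). For the afferent
class this is the gradient of the Kullback–Leibler divergence between
the Poisson laws of the output rate and its prediction. Two
sign-constrained variants are included: `"signed"` (separate
non-negative `M_exc`, `M_inh`, `G` on a fixed random partition of neuron
pairs) and `"DL"` (distinct excitatory and inhibitory populations with
two inhibitory pathways — one predicting jointly with excitation, one
alone). Trained networks form stimulus-specific assemblies; after input
removal and a recovery period, they replay these assemblies
spontaneously, and the replay statistics (population-rate ratios,
activity ratio of a decision network) encode the stimulus
probabilities. See the methods vignette
(`vignettes/replaynet-methods.Rmd`) for the full model description and
the package's design decisions.

## Worked example

Train the scaled mixed-sign network on two stimuli presented 30% / 70%
of the time, then look at what the spontaneous activity and the learned
weights remember:

```r
library(replaynet)
set.seed(1)
fit <- replaynet(pattern_spec(2, probabilities = c(0.3, 0.7)),
                 n_neurons = 100, learn_ms = 3e5)
fit
#> Predictive-plasticity replay network (nDL)
#>   N = 100 neurons, K = 200 inputs, 2 stimuli
#>   trained 300 s; empirical stimulus frequencies: 0.31, 0.69
#>   assemblies: 31, 65  unassigned: 4

spont <- simulate(fit, duration_ms = 1e5)
spont
#> spontaneous epoch, 100 s: mean rate 4.43 Hz
#>   assembly population rates (Hz): 178.8, 244.0

normalized_excitatory_incoming_weights(fit$weights$M, fit$assignment)
#> [1] 0.2403 0.7597
```

Reading the output: the network split into two assemblies whose sizes
(31 vs 65 neurons) track the 30/70 presentation probabilities, and the
normalized within-assembly excitatory weights (0.24 / 0.76) approximate
them closely — the learned weights store the prior. The spontaneous
population rates lean the same way (179 vs 244 Hz); at this scaled
network size the rate-based readout is compressed relative to the
weight-based one (see the vignette's finite-size discussion).

The decision-task experiment summarizes replay by the activity ratio
`AR = r_R / (r_R + r_L)`; `run_decision_task(c(0.8, 0.2), coh_grid =
seq(-0.5, 0.5, 0.25))` trains under a biased protocol and returns the
spontaneous AR together with the psychometric "choices to right" curve
from evoked probes.

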