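---
title: "Predictive plasticity and probabilistic replay: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive plasticity and probabilistic replay: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`replaynet` simulates recurrent networks of Poisson spiking neurons in
which every synapse follows one predictive plasticity principle: each
class of connections onto a neuron maintains its own linear "prediction"
of the neuron's firing rate, and weights change in proportion to the
prediction error times the presynaptic activity trace. Networks trained
on repeated stimulus patterns segment them into stimulus-specific cell
assemblies and, once the input is removed, spontaneously replay those
assemblies with population rates that reflect the stimulus probabilities
experienced during learning.

## Dynamics

Each neuron $i$ has a membrane potential that is a weighted sum of
presynaptic traces. A spike at time $t'$ contributes
$\varepsilon(t - t') = e^{-(t-t')/\tau}$ to its synapse's trace
($\tau = 15$ ms), so the afferent trace vector $x$ and recurrent trace
vector $y$ are leaky sums of spikes with unit jumps. In the mixed-sign
(nDL) variant

$$u_i = \sum_k W_{ik} x_k + \sum_k (M_{ik} - G_{ik})\, y_k,$$

with signed afferent weights $W$, signed recurrent weights $M$, and a
non-negative inhibitory-only matrix $G$. The instantaneous rate is a
sigmoid of $u_i$ with maximum $\varphi_0 = 50$ Hz, slope
$g\beta_0 = 15$ and a homeostatically regulated threshold (below), and
spikes are drawn per 1-ms Euler step as Bernoulli events with
probability $f_i\,\mathrm{d}t/1000$ — the standard discretization of an
inhomogeneous Poisson process (maximal probability 0.05 per step).

Two further variants restrict synaptic signs. The sign-constrained
variant splits the recurrent connections into non-negative matrices
`M_exc`, `M_inh` and `G` over a fixed random partition of neuron pairs
(half excitatory, a quarter each for the two inhibitory classes). The
Dale's-law (DL) variant has distinct excitatory and inhibitory neuron
pools; inhibitory neurons reach each target population through two
paths: path 2 predicts jointly with excitation and learns to mediate
competition between assemblies, path 1 predicts on its own and learns to
balance excitation within assemblies.

## Plasticity

All rules share one error factor,

$$\mathcal{E}(f, v) = \varphi_0^{-1}
  \Big(1 - \frac{\varphi(v)}{\varphi_0}\Big)\,[f - \varphi(v)],$$

where $\varphi$ is the static sigmoid (midpoint $g\theta_0 = 3$, slope
$g\beta_0 = 15$) and $v$ is the prediction of the connection class being
updated ($v^W = Wx$, $v^M = My$, $v^G = Gy$ in the nDL variant). Each
update is $\eta\,\mathcal{E}(f_i, v_i)\,(\text{presynaptic trace})_j$
with $\eta = 10^{-4}$; matrices that must stay non-negative are
truncated at zero after every step. The presynaptic factor is part of
every rule here: it is what the gradient derivation produces, it is how
the sign-constrained and DL rules are defined, and without it the
inhibitory matrix could only drift uniformly. For the afferent rule we
verify in the test suite that the update equals the finite-difference
gradient of the instantaneous Kullback–Leibler divergence between the
Poisson laws of the output rate and the afferent prediction, up to the
constant prefactor $\eta/(g\beta_0\varphi_0)$.

In the sign-constrained variant the excitatory and first inhibitory
matrices share one joint prediction `v(M_exc) - v(M_inh)` and move in
opposite directions, so the same error strengthens excitation and
weakens that inhibition. In the DL variant the path-2 matrices
(`M_XE`, `G2_XI`) behave the same way around their joint prediction,
while path 1 (`G1_XI`) learns alone against its own prediction.

Initial weights: $W$ and $M$ are zero-mean Gaussian with variances
$0.1/\sqrt{K}$ and $0.1/\sqrt{N}$ (we read the stated spread literally
as a variance and expose it as `init_scale`); $G$ starts uniformly at
$1/\sqrt{N}$. Sign-constrained matrices start from the absolute values
of the same Gaussians on their masks.

## Homeostatic excitability — what we changed and why

The response function regulates excitability through a per-neuron
variable $h$: the firing threshold is $g\theta_0 h$, so a history of
large potentials (large $h$) lowers excitability and a quiet stretch
(decaying $h$, time constant $\tau_h = 10$ s) restores it. At $h = 1$
the dynamic sigmoid coincides with the static one used inside the
plasticity rules, which is also how we initialize $h$.

Two design decisions here deserve a prominent record, because the
natural alternative formulations of the homeostatic regulation fail
structurally and the choices are therefore forced by the dynamics.

1. **The gain is not rescaled by $1/h$.** If both the threshold and the
   gain scale with $h$ (threshold up, gain down), their product — the
   sigmoid's exponent at $u = 0$ — is a constant
   $g^2\beta_0\theta_0 = 45$, so the at-rest firing rate is pinned at
   $\varphi_0 e^{-45} \approx 10^{-18}$ Hz *regardless of* $h$. A
   network whose activity has died can then never re-ignite, and
   input-free replay with quiet gaps is impossible; we verified this
   empirically (a trained network is completely silent over 100-s
   spontaneous epochs under the rescaled-gain rule). Keeping the gain
   fixed at $g\beta_0$ makes the at-rest rate
   $\varphi_0/(1 + e^{45h})$ — vanishing while the network is adapted,
   but recovering as $h$ decays, which is exactly the excitability
   recovery that precedes replay.

2. **$h$ tracks the potential with a finite rise time.** $h$ relaxes
   upward toward $u/(g\theta_0)$ with a rise constant
   $\tau_r = 1000$ ms and decays with $\tau_h$ otherwise. The
   normalization by the resting threshold makes the learned operating
   point self-consistent ($h \to 1$ when the driven potential reaches
   the static midpoint). The finite rise time is essential: with an
   instantaneous jump the threshold pins to the momentary *peak* of
   $u$, and because the Poisson input traces make $u$ fluctuate by
   roughly 8% within a presentation while the sigmoid slope is 15, the
   neuron is silenced everywhere except at the peak — learning stalls
   at sub-Hz rates (we measured 0.1 Hz). $\tau_r$ is chosen once, on
   the argument that the set-point should average over several 100-ms
   presentations (so $\tau_r \gg 100$ ms) while remaining fast against
   the forgetting timescale ($\tau_r \ll \tau_h$); we did not revisit
   it afterwards. During spontaneous activity the same two timescales
   give replay its event structure: a burst drives $h$ up over about a
   second and self-terminates, and the slow decay re-arms the
   assembly.

$h$ is clamped below at `h_floor = 1e-2`, which acts as the resting
excitability bound: during long input-free stretches the $h$ of
suppressed neurons decays onto the floor, so the clamp is a functional
part of spontaneous dynamics rather than a rare numerical guard. The
engine counts clamp events and reports them with every phase
recording.

## Order of operations

One Euler step is: update $x$ from the input spikes (all-zero in
spontaneous mode); compute $u$ and the per-class predictions from the
current $x$ and the previous step's $y$; update $h$ from the
current-step $u$; evaluate $f$; draw spikes; apply all enabled weight
updates synchronously using the same-step $f$, predictions, and traces;
finally update $y$ from the new spikes. Self-connections exist and are
plastic. The compiled loop (RcppArmadillo) and the pure-R reference
loop built from the exported single-step operations consume the RNG
stream in the same order and are compared bit for bit in the tests.

# The stimulus generator

All inputs are internally generated Poisson spike trains; the generator
is first-class, tested code.

* **Pattern protocol** (`pattern_spec()`): $n$ groups of 100 input
  neurons; one pattern at a time fires its group at 50 Hz for 100 ms,
  presentations are separated by 100-ms gaps, and all input neurons
  (including pattern members) fire at 2 Hz background between
  presentations. Identities are i.i.d. draws from the configured
  probabilities (or a fixed cycle). We use constant gaps; irregular
  gaps are a straightforward extension the protocol object already
  accommodates via its event list. Overlapping groups share a
  configurable fraction of members.
* **Decision protocol** (`coherence_spec()`): R and L pools of 100
  inputs; a stimulus of coherence $c \in [-0.5, 0.5]$ drives the pools
  at $(c + 0.5)\,r_\max$ and $(-c + 0.5)\,r_\max$ with
  $r_\max = 50$ Hz. Training presents the fully coherent stimuli
  ($c = \pm 0.5$, so the opposite pool is silent during a stimulus)
  with the protocol probabilities, re-using the 100 ms / 100 ms timing
  of the pattern protocol since the exact trial structure of the
  learning phase is not otherwise constrained.
* **Conditioned protocol** (`conditioned_spec()`): two stimulus pairs
  feed two equal subnetworks; the B-stimulus in each slot is drawn from
  the row of a conditional probability table selected by the
  simultaneous A-stimulus. The afferent matrix is masked so groups 1–2
  reach only subnetwork A and groups 3–4 only subnetwork B, while the
  recurrent matrices stay all-to-all — the conditional structure must
  therefore be carried by learned recurrent synapses.

What the generator does *not* emulate: naturalistic stimulus
statistics, rate gradients within a group, temporally structured
(non-Poisson) spike trains, or session-to-session variability. Passing
tests therefore demonstrate that the learning rules recover the
probabilistic structure of this idealized protocol family, not that
they would do so for natural stimuli.

# Experiments and measurements

The canonical pipeline (`replaynet()`, `run_experiment()`) is: 300 s of
learning (scaled conditions; see below), input removal, 20 s of
recovery with all plasticity off, then a 100-s input-free spontaneous
epoch for replay metrics and short evoked probes (plasticity off, 20
presentations per stimulus) for assembly identification. A neuron joins
the assembly of its best-driving stimulus if its selectivity index
(best minus second-best over their sum) reaches 0.3; the threshold is a
package default, exposed in the configuration, and the assignment-based
metrics exclude unassigned neurons from every numerator and
denominator. Replay metrics follow the printed definitions: per-neuron
rates are spike counts over the epoch divided by its length; the
firing-rate, assembly-size and assembly-activity ratios compare a
target assembly with the mean of the others; the decision experiments
summarize replay by the activity ratio
$\mathrm{AR} = r^{pop}_R / (r^{pop}_R + r^{pop}_L)$, and the
psychometric "choices to right" is $\mathrm{AR} \times 100$ for evoked
probes across a coherence grid. Pairwise spontaneous correlations use
Pearson correlation of 20-ms binned counts (bin width is a package
default; zero-variance neurons are flagged and their correlations set
to 0).

Plasticity during the measured spontaneous epoch is off by default so
that the metrics describe a fixed learned network; the runner accepts
any subset of matrices for phases where continued learning is the
object of study (e.g. the inhibitory-plasticity ablation below).

## Ablations

* Fixed homeostatic variable. Freezing `h` for the *whole* run
  (`fixed_h = TRUE` in `replaynet()`) leaves the network silent: with
  the threshold stuck at its resting value the initial weights never
  drive any spiking, which demonstrates the variable's
  trivial-solution-avoidance role during learning. The sampling
  ablation therefore trains normally and freezes `h` at its
  post-recovery value only for the measured spontaneous epoch
  (`simulate(fit, fixed_h = TRUE)`): the network still replays, but
  without the slow excitability regulation the probability estimate
  degrades.
* Frozen inhibitory plasticity: continue the spontaneous phase with
  `plastic = c("W", "M")` (inhibition frozen) versus the control
  `c("W", "M", "G")`; the within-minus-between contrast of the
  recurrent matrix decays faster without the continuous re-balancing by
  `G`.
* `remove_between_assembly_excitation` zeroes positive cross-assembly
  recurrent weights at probe time; replay statistics survive because
  replay is driven by within-assembly recurrence.

# Problem sizes, tolerances and reproducibility

All shipped experiments run at the scaled conditions N = 100 network
neurons, 100 input neurons per group, 2–5 patterns, 300 s of learning,
100-s analysis epochs; the full-size conditions (N = 500, 1000 s) are a
parameter change away but are not exercised in the test suite. All
randomness flows through R's global RNG; every experiment takes a
single seed, and identical seeds give bit-identical rasters, weight
trajectories and reports (asserted in the tests). Numerical guards:
non-finite membrane potentials abort a run with a diagnostic rather
than propagate; sigmoid overflow underflows safely to 0; per-step spike
probabilities are validated against 1.

## What the scaled network does and does not reproduce

At these scaled conditions the package reproduces: assembly
self-organization with sizes tracking stimulus probabilities;
within-assembly excitatory and inhibitory structure (and, in the
sign-constrained variant, the division of labour in which `M_inh`
concentrates between assemblies while `G` concentrates within; in the
DL variant, path-1 lateral inhibition concentrated within assemblies
and path-2 between); within-assembly spontaneous correlations exceeding
between-assembly ones; an unbiased spontaneous activity ratio of 0.5
after 50:50 training; and normalized within-assembly excitatory weights
that approximate the stimulus probabilities.

One quantitative aspect is systematically weakened by the small network:
per-synapse within-assembly weights scale inversely with assembly size,
so members of rarer (hence smaller) assemblies receive larger
per-spike recurrent kicks and fire somewhat more per neuron during
spontaneous epochs. This partially offsets the assembly-size code and
compresses spontaneous activity ratios toward 1 — after 80:20 training
we measure AR around 0.65–0.71 across seeds rather than 0.8, and the
assembly-activity ratio for a probability ratio of 2 falls short of 2.
The weight-based probability code (normalized within-assembly
excitatory weights) is unaffected. The relative size of the shot-noise
kicks shrinks as assemblies grow, so this is a finite-size property of
the scaled conditions, not of the learning rules; we report the
measured values as they are rather than adjusting the conditions to
mask the effect.

The conditioned two-subnetwork experiment shows the sharpest form of
this balance limitation. After conditioned training the *excitatory*
cross-subnetwork couplings order correctly with the conditional
probabilities (the mean `M` from the S1-assembly onto the S4-assembly
exceeds that onto the S3-assembly, and mirrored for S2), so the
conditional structure is genuinely learned into the recurrent weights.
But the balancing inhibition `G` grows in proportion to the same
co-activation statistics, and at this network size the net coupling
`M - G` between co-trained assemblies ends up slightly *negative* —
probing with S1 alone therefore fails to re-activate the B-side
assemblies in proportion to the trained conditionals (the measured S4
fraction falls well below the trained 2/3, and can invert). We verified
that this is not a probe-duration or adaptation artifact (early and
late probe windows agree). The rate-based conditional readout is
reported as measured.

# Known limitations

* Dendrites are not modelled explicitly; each connection class is a
  single linear compartment with its own prediction.
* The model is rate-to-Poisson with 1-ms Bernoulli thinning — no
  refractoriness, no conductances, no integrate-and-fire reset.
* The rise time constant $\tau_r$ of the homeostatic tracker is a
  package-level design choice (see above); behaviour is insensitive to
  factor-of-two changes but we have not mapped its full range.
* Weight snapshots use plain CSV matrices plus JSON metadata rather
  than a binary container, keeping artifacts text-only and
  dependency-free.
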