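---
title: "Models and methods behind dualHebb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualHebb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualHebb)
```

dualHebb simulates a two-layer rate network that infers a discrete hidden
state from noisy population input, and asks what should be stored in
synaptic *weights* versus in the binary *wiring diagram* when connectivity
is sparse and spines turn over. This vignette explains the model, the
estimators, the tunable parameters and their defaults, the numerical
choices, and — importantly — which aspects of the closed-form theory the
package can verify quantitatively and which only qualitatively.

## The generative model and the decoding network

At every time step one hidden state $s^t \in \{1,\dots,p\}$ is drawn
uniformly. Input neuron $j$ fires at a rate drawn from a one-parameter
exponential family with mean parameter $\theta_{j\mu}$ when $s^t = \mu$:

$$f(r \mid \theta) = \exp[h(\theta)\,g(r) - A(\theta) + B(r)],$$

with the Gaussian family ($h(\theta)=\theta/\sigma_X^2$, additive noise of
scale $\sigma_X$) used for all analytics and the Poisson family
($h(\theta)=\log\theta$, integer counts) as the discrete alternative. The
natural parameters $q_{j\mu}=h(\theta_{j\mu})$ measure how much evidence
input $j$ carries for state $\mu$.

Tuning matrices are random: raw entries from a truncated normal
$N(\mu_M,\sigma_M)$ on $[0,\infty)$ (Gaussian) or a truncated log-normal
(Poisson), then normalized per state so the root-mean-square (Gaussian) or
mean (Poisson) rate equals $r_X^o$. Sampling is by rejection, not clipping:
clipping would put an atom of probability at exactly zero response, which
the closed-form moment calculations do not assume. The per-state
normalization is exact, a point that matters below.

Output neurons form membrane potentials
$v_i = \sum_j c_{ij}(w_{ij} g(r_{X,j}) - h_w)$ and fire through a global
log-sum-exp inhibition, i.e. a softmax: rates are positive and sum to
$r_Y^o$, implementing a probabilistic winner-take-all. Each output neuron is
nominally selective for state $\sigma_i = \lfloor p\,i/N\rfloor$. For an
all-to-all network with $w_{ij} = q_{j\sigma_i}$ and $h_w = 0$, the summed
rate of each selectivity group equals the exact Bayes posterior, to machine
precision, because the per-state normalization equalizes the log-partition
sums $\sum_j \alpha(q_{j\mu})$ across states. This identity is the
package's strongest internal oracle and is tested at $10^{-10}$.

Two numerical guards: softmax is always computed with a max shift, and
membrane potentials are floored at $\max_\ell v_\ell - |v_d|$ (default
$v_d = 60$) *before* the inhibition term, so rate conservation is exact
even when clipping engages. The floor only touches neurons whose posterior
weight is below $e^{-60}$, so it never affects decoding at double
precision.

## Static coding strategies

Five constructors write the tuning into a sparse network: weight coding
(random wiring at density $\rho = \gamma\bar q$, weights
$q_{j\sigma_i}/\rho$), connectivity coding (constant weights $1/\gamma$,
wiring probability $\min(\gamma q_{j\sigma_i},1)$), dual coding (both),
cut-off coding (optimal weights, each output keeps its
$\mathrm{round}(M\rho_o)$ largest, ties broken at random so the count is
exact), and random coding (the density-matched null). Thresholds follow the
convention $h_w = \bar q/\gamma$ for the tuned strategies and
$\bar q/\rho_o$ for cut-off/random; under input-dependent noise $\bar q$ is
computed with the baseline $\sigma_X$, which keeps the threshold from being
dominated by a handful of low-noise inputs.

Under input-dependent noise the probability cap $\min(\gamma q, 1)$ makes
the realized dual-coding density substantially larger than the nominal
$\gamma\bar q$. Where a density-matched comparison against cut-off coding
is needed (the robustness experiments), $\gamma$ is calibrated numerically
so the realized expected density hits the target; the constructors
themselves keep the stated normalization.

The structured "constant-response" model — a quarter of inputs at a fixed
high level, the rest binary high/low per state — needs concrete response
levels. The defaults are $\theta_{const}=1.5$, $\theta_{high}=1$,
$\theta_{low}=0.25$, chosen once against a neutral target: the dense Bayes
decoder must solve the task (~100% here) while the constant group still
tops every informative input in optimal-weight ranking. This is the regime
the model is meant to probe: weight-ranked pruning then keeps only
uninformative synapses (accuracy at chance), while probabilistic dual
wiring retains a workable fraction of informative ones.

## The plasticity rules

Weight plasticity is Hebbian with a homeostatic term,

$$\Delta w_{ij} = \frac{\eta_X}{\gamma}\Big(r_{Y,i}\big[g(r_{X,j}) -
\alpha'(\bar\rho\, w_{ij})\big] + b_h\big[r_Y^o/N - r_{Y,i}\big]\Big),$$

applied on existing connections, with weights floored at $10^{-12}$ so they
stay strictly positive. $\bar\rho$ is the mean connectivity measured once,
from the initial wiring diagram. The first term is stochastic gradient
descent on the KL divergence between the true input distribution and the
one the weights encode; its fixed point is the weight coding
$w_{ij} \to q_{j\mu}/\bar\rho$, which the tests verify to ~10% relative
error on strongly tuned inputs. The homeostatic term pulls every output
toward the uniform rate and is what lets the population self-organize a
full cover of the states.

Wiring plasticity maintains a connection probability $\rho_{ij}$ for every
*potential* synapse. The dual Hebbian rule updates it with the same
Hebbian form, $\Delta\rho_{ij} = \eta_\rho r_{Y,i}[g(r_{X,j}) -
\alpha'(\rho_{ij} w_o)]$ (updated for all pairs — the rule has no gate on
the synapse existing; for silent outputs the update is numerically zero
anyway). The approximated rule drops all activity dependence: existing
spines relax toward a size-proportional probability $\gamma^2 w_{ij}$,
absent pairs sit at the constant $\gamma^2 w_o$. Rewiring is a
detailed-balance birth–death process: per step, creation with probability
$\rho_{ij}/\tau_c$ and elimination with probability
$(1-\rho_{ij})/\tau_c$, so the stationary occupancy of every pair equals
$\rho_{ij}$ exactly — verified elementwise by a $\chi^2$ test against a
frozen probability matrix. New spines are born at
$w = (1+\sigma_w^{init}\zeta)\,w_o$; with the default
$w_o = r_X^o/\gamma$ and $r_X^o = 1$ this coincides with the
$(1+\sigma\zeta)/\gamma$ convention used elsewhere.

The update order within a step is fixed (and not otherwise constrained by
the theory): dynamics → weight update → probability update → rewiring.

The per-step loop is compiled. Two exact accelerations are worth knowing
about: rewiring events are sampled by thinning (binomial candidate count at
the maximal per-pair rate, then per-candidate acceptance), which is
distributionally identical to sweeping all $NM$ pairs; and Hebbian terms
are skipped for outputs whose softmax rate is below $10^{-14}$, whose
cumulative effect over $10^6$ steps is below $10^{-12}$ in any weight. A
pure-R reference step reproduces the compiled loop draw-for-draw (tested to
bitwise agreement), which pins down the exact stochastic process being
simulated.

## Evaluation

*Accuracy* uses a bootstrap split: selectivity groups are measured from one
window of $T_o = 10^3$ steps (each neuron goes to the state maximizing its
conditional mean rate, ties to the lowest index), and the following window
is scored: a step is correct when the selective group's mean rate strictly
exceeds every other group's (ties and empty groups count as failures).

*Transfer entropy* $\langle H(s) - H(s\mid r_X, C)\rangle$ is Monte-Carlo
averaged with each output's posterior computed from its connected inputs
using the true model parameters, group-averaged; it is bounded by
$\log p$ and checked against a two-dimensional quadrature oracle on a tiny
model.

*Model error* reconstructs tuning from the network (combined, wiring-only,
or weight-only estimators), rescales each state to the model's RMS rate
(so global weight rescalings cancel) and reports the mean squared error.

*Connectivity optimality* measures
$I(C_{all}, C)$, the state-averaged KL divergence between group posteriors
of the full and the pruned network, integrating the Gaussian noise in
closed form; a Monte-Carlo mode cross-checks it. Per-connection information
gains average the drop in $I$ from adding one synapse to random structures,
and a row-swap hill climber provides lower bounds on the best achievable
structure (monotone by construction, best-of-restarts).

## The closed-form performance theory, and its limits

For the Gaussian model the membrane potential of a selective and a
non-selective output is approximately bivariate normal, with closed-form
moments under weight and connectivity coding; pairwise error
$\epsilon_w = \Phi(-\Delta\mu/\sigma_\Delta)$ and accuracy
$(1-\epsilon_w)^{p-1}$. Two caveats are documented deliberately, verified
numerically in this package's tests rather than hidden:

1. **Moment ensembles.** The variance formulas are exact for an ensemble
   in which tuning entries are i.i.d. *Gaussian* with the truncated
   distribution's mean and SD; the covariance formulas mix in terms from a
   fixed-tuning ensemble. The actual generator pins each state's sum of
   squares exactly and has heavier-than-Gaussian fourth moments, so its
   second moments deviate from the closed forms by several percent (with
   opposite signs at sparse vs dense density). The deviations largely
   cancel in the variance of the *difference* $u_{sel}-u_{nonsel}$, which
   is why accuracy-level predictions remain useful. The moment tests
   compare against the faithful generator at three standard errors and the
   variance components fail exactly as this analysis predicts;
   `sample_membrane_potentials(tuning = "iid_gaussian")` exposes the
   derivation ensemble, under which the weight-scheme algebra verifies.
2. **Independent-distractor approximation.** $(1-\epsilon_w)^{p-1}$ treats
   the $p-1$ distractors as independent, but all outputs share the same
   input-noise realization; the true multi-distractor accuracy is far
   higher at intermediate density (e.g. 0.35 vs 0.07 at $\rho = 0.1$),
   even when the pairwise $\epsilon_w$ itself verifies to three decimals.
   The *ordering* — connectivity coding beats weight coding when sparse,
   with the gap closing toward dense wiring — is robust in both analytics
   and simulation and is what the theory is used for.

The information-capacity calculus is exact: $I_C = \log\binom{MN}{\rho MN}$
nats for wiring, $I_w = \rho MN\log b$ for weights with $b$ distinguishable
states, break-even at $\log_2 b^* = H(\rho)/(\rho\ln 2)$ bits — about 5.46
bits at the 6% density typical of hippocampal CA3→CA1 wiring, above current
estimates of per-synapse weight precision, which is the argument that
wiring must carry information in sparse cortex.

```{r capacity}
info_capacity(200, 100, rho = 0.06)[c("break_even_b", "break_even_bits")]
```

## Protocols and scaled presets

The learning experiments in this package run at the reference network size
($M = 200$, $N = 100$, $p = 10$) but at reduced durations, chosen once from
timescale analysis:

* **Static learning comparison** — $5\times10^5$ steps at $\gamma = 0.1$,
  $\tau_c = 10^5$ (five rewiring time constants); the weight-only control
  is rebuilt at the dual run's final density so the comparison is
  density-matched.
* **Dynamic environment** — epochs of $T_2 = 10^4$ steps,
  $\tau_c = 2\times10^4$ (wiring integrates over a couple of epochs
  without fully tracking the variable component), five unscored burn-in
  epochs before ten scored ones. Early-phase accuracy is scored against
  selectivity measured *before* the switch — the trailing-window bootstrap
  — which is what makes the trough a probe of structure retained across
  the switch. At this reduced scale the weight-only rule still drifts
  upward slowly (a flat weight-only trough is a long-run steady-state
  property, emerging only over many tens of epochs), so the package's claim is the contrast: the dual rule's
  trough climbs faster, and its wiring correlates with the constant
  component while its weights track the variable one.
* **Spine protocols** — days of $10^4$ steps with all rates scaled to
  preserve their fraction of a day: $\eta_X = 0.1$, $\eta_\rho = 10^{-3}$,
  $\tau_c = 3\times10^4$ (0.1-day probability relaxation, 3-day rewiring
  constant, matching the full-scale $10^5$-step-day parameterization).
  Scaling only the day length and not the rates slows every within-day
  process tenfold and qualitatively breaks the size-vs-drift statistics —
  the package deliberately does not do that. The twenty-day burn-in before
  day 0 ensures the control condition is converged, which is what makes
  "training" a retraining; survival statistics use day-boundary snapshots
  only, ignoring within-day transients, as chronic imaging does. The
  fivefold elimination increase is applied only in the test-phase
  performance runs, not in the survival comparisons.

What the synthetic generator does *not* emulate: temporally correlated
stimuli, non-uniform state priors, multi-synapse contacts, dendritic
geometry or distance-dependent wiring costs, and any biophysical spiking.
Passing tests therefore show that the learning rules and statistics behave
as the theory says under the stated generative model — not that cortical
data would.

## Degenerate inputs and tie-breaking, in one place

Rejection sampling for truncations; selectivity ties to the lowest state;
accuracy ties count as failures; empty selectivity groups are scored as
failures (and are an error for model-error estimation, which needs every
state represented); cut-off ties are broken uniformly at random to keep
the in-degree exact; weights are floored at $10^{-12}$, probabilities
clipped to $[0,1]$; zero-norm update directions are skipped in the
gradient-alignment estimate; capacity at $\rho \in \{0,1\}$ returns zero
with a boundary flag rather than NaN.
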