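# dualHebb

Cortical circuits are sparsely wired, and their spines — the anatomical
substrate of excitatory synapses — are created and eliminated throughout
adult life. That raises a quantitative question: when synaptic *weights*
already provide a rich, graded storage medium, what is the binary *wiring
diagram* for, and how could local, stochastic spine turnover ever build a
useful one? `dualHebb` is an R package for studying this question in a
tractable setting: a two-layer rate network that infers a discrete hidden
state from noisy population input, where every ingredient — the generative
model, the decoding dynamics, the coding strategies, the learning rules,
and the information-theoretic evaluation — is explicit and testable. It is
aimed at computational neuroscientists who want a reproducible simulator
and analysis toolkit for weight-versus-wiring questions.

## The model in brief

At each step a hidden state $s^t \in \{1,\dots,p\}$ is drawn uniformly and
$M$ input neurons fire from an exponential-family emission model,
$r_{X,j} \sim f(r \mid \theta_{j s^t})$ — Gaussian
($\theta_{j\mu} + \sigma_X \zeta$) or Poisson counts. $N$ output neurons
integrate through a binary connection matrix $C$ and weights $W$,

$$r_{Y,i} = r_Y^o\, \exp\Big[\sum_j c_{ij}\big(w_{ij}\, g(r_{X,j}) - h_w\big)
  - I_{inh}\Big],$$

with a global log-sum-exp inhibition $I_{inh}$ (a softmax, i.e. a
probabilistic winner-take-all). For all-to-all wiring and weights equal to
the natural parameters $q_{j\mu} = h(\theta_{j\mu})$, the group-summed
output rates equal the exact Bayes posterior over states.

When wiring is sparse the tuning can be coded in the weights, in the
connection probabilities, in both ("dual coding"), or by pruning the
smallest weights; the package builds all of these and evaluates them by
bootstrap decoding accuracy, transfer entropy, model error, and
KL-divergence measures of connection-structure optimality, alongside
closed-form membrane-potential statistics. Learning combines Hebbian
weight plasticity with a homeostatic term and *dual Hebbian wiring
plasticity*: a per-pair connection probability $\rho_{ij}$ updated by
pre/post activity (or by a spine-size proxy), realized by detailed-balance
rewiring — creation with probability $\rho_{ij}/\tau_c$, elimination with
probability $(1-\rho_{ij})/\tau_c$ — so the stationary occupancy of every
potential synapse equals $\rho_{ij}$. Experiment drivers reproduce
dynamic-environment learning and motor-training spine-turnover protocols
with survival statistics.

## Worked example

```r
library(dualHebb)
set.seed(7)

# A 10-state world observed through 200 noisy inputs
m <- make_gaussian_model(p = 10, M = 200)

# Dual coding at ~10% connectivity: probabilities and weights both tuned
net <- build_dual_coding(m, gamma = 0.12)
mean(net$C)                                  # 0.103  realized connectivity
bootstrap_accuracy(m, net)$accuracy          # 0.933  decoding accuracy
transfer_entropy(m, net, n_samples = 500)    # 1.33 nats (log p = 2.30)

# Learn weights and wiring jointly from a random sparse network
net0 <- build_plastic_network(m, gamma = 0.1)
cfg  <- plasticity_config("dual_hebbian", tau_c = 1e5, eta_rho = 0.001)
fit  <- train(net0, m, steps = 2e5, cfg, trace_every = 5e4)
fit$trace
#>     step connectivity mean_weight
#> 1  50000      0.08395        14.7
#> 2 100000      0.08590        16.0
#> 3 150000      0.08550        16.6
#> 4 200000      0.08805        16.7
bootstrap_accuracy(m, fit$network)$accuracy  # 0.787 after 2e5 steps
c(fit$n_created, fit$n_eliminated)           # 3028 2965: turnover balances

# How many weight states before wiring stops being the better store?
info_capacity(200, 100, rho = 0.06)$break_even_bits   # 5.46 bits/synapse
```

The trace shows what the dual Hebbian rule is supposed to do: spine
creation and elimination balance (total connectivity drifts by only a few
percent) while accuracy climbs well above the matched weight-only network,
because the wiring concentrates on informative inputs. The final line is
the capacity calculus: at 6% connectivity, a synapse would need about 5.5
reliably distinguishable weight levels before graded weights out-store the
wiring diagram — an argument that sparse wiring itself carries
information.

See the methods vignette (`vignettes/dual-hebbian-methods.Rmd`) for the
model details, parameter conventions, scaled experiment presets, and a
candid account of which of the closed-form approximations hold quantitatively and
which only qualitatively.

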