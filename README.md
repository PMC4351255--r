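# augmentrl

Trial-and-error learning of working memory in a three-layer neural
network, implemented with biologically local plasticity: SARSA(λ)
action-value learning realised through synaptic **tags** and **traces**
that are gated by attentional feedback from the selected action and by a
globally broadcast reward-prediction error (the AuGMEnT learning scheme).

The package is for computational neuroscientists who want to simulate how
neurons in association cortex acquire task-tuned persistent activity —
category boundaries, integrated probabilistic evidence, or analog scalar
memories — purely from delayed rewards, and to reproduce the convergence
statistics and emergent representations reported for four classic primate
experiments.

## The model

Sensory input reaches the network through *instantaneous* units `x(t)` and
paired *transient* units that encode positive and negative stimulus
changes, `x⁺(t) = [x(t) − x(t−1)]₊` and `x⁻(t) = [x(t−1) − x(t)]₊`.

The association layer contains *regular* units driven by the instantaneous
inputs,

    y_j^R = σ( Σ_i v_ij^R x_i + v_0j ),    σ(a) = 1 / (1 + exp(θ − a)),

and *memory* units that integrate the transient inputs over the trial,

    inp_m(t) = inp_m(t−1) + Σ_l v_lm^M x'_l(t),    y_m^M = σ(inp_m),

so a stationary stimulus is stored as persistent activity rather than
integrated as a ramp. A layer of Q-value units estimates action values

    q_k = Σ_j w_jk^R y_j^R + w_0k + Σ_m w_mk^M y_m^M,

and a Max-Boltzmann controller selects the greedy action with probability
1 − ε, otherwise sampling from `P(k) ∝ exp(q_k)`.

Learning combines four factors. After action `a` is selected, feedback
weights `w'` from the winning Q-unit create synaptic tags:

    ΔTag_jk = −α·Tag_jk + y_j z_k                     (output synapses)
    ΔTag_ij = −α·Tag_ij + x_i σ'(inp_j) w'_aj         (onto regular units)
    ΔsTrace_lm = x'_l ;  ΔTag_lm = −α·Tag_lm + sTrace_lm σ'(inp_m) w'_am

with tag persistence `α = 1 − λγ`, so tags decay by the factor λγ per step
exactly as SARSA(λ) eligibility traces. Every step the SARSA
reward-prediction error

    δ(t) = r(t) + γ q_a'(t) − q_a(t−1)

is broadcast globally and each weight changes as `Δw = β δ Tag`. For λ = 0
this update is exactly one step of gradient descent on the squared
prediction error of the sampled transition — the package ships a
finite-difference oracle (`gradient_check()`) that verifies the
equivalence to machine precision.

Reference parameters: β = 0.15, λ = 0.20, γ = 0.90, ε = 0.025; 3 regular,
4 memory and 3 Q-value units; weights initialised uniformly on
[−0.25, 0.25]. The sigmoid offset defaults to θ = 2.5.

## The tasks

Four discrete-time environments share a reset/step interface and a common
trial skeleton (acquire fixation or key-hold, sample stimulus with a small
shaping reward `r_i = 0.2`, memory delay, go phase, full reward
`r_f = 1.5` for the correct choice):

* **saccade** — memory pro-/antisaccade: fixation-mark colour selects the
  rule, the cue location must be remembered across the delay (plus a
  pro-only variant where colour is irrelevant);
* **category** — delayed match-to-category over twelve motion directions
  with circular-Gaussian population coding and a 0°/180° boundary;
* **classification** — probabilistic weighted-symbol decisions with trump
  symbols and an eight-level shaping curriculum;
* **vibrotactile** — two-flutter frequency comparison with sigmoidal
  frequency tuning and rate noise, in variable-F1, fixed-F1 and
  block-training protocols.

## Worked example

Train twenty independent networks on the saccade/antisaccade task:

```r
library(augmentrl)
e <- run_experiment("saccade", n_networks = 20, seed = 42)
print(e)
#> experiment 'saccade': 20/20 networks converged (100.0%)
#>   median trials to criterion: 4,879.5
#>   median fixation milestone: 346.5 trials
```

All twenty networks reach the criterion (≥ 90% correct over the last 50
trials of each of the four trial types, confirmed by a frozen verification
battery) after a median of ~4,900 trials; the fixation shaping reward is
mastered within a few hundred trials.

Train one network on the variable-F1 vibrotactile task and ask how its
memory units encode the two frequencies during the comparison phase:

```r
r <- train_network("vibrotactile", seed = derive_seed(42, 3),
                   keep_net = TRUE)
r$trials
#> [1] 2425
freeze_network(r$net)
f <- f1f2_regression(r$net, r$env)   # activity = a1*F1 + a2*F2 + b
subset(f, group == "memory")
#>  unit  group      a1      a2       b
#>     4 memory -0.0096  0.0045  0.3118
#>     5 memory  0.0037  0.0007 -0.0334
#>     6 memory -0.0003 -0.0027  0.9802
#>     7 memory -0.0175  0.0191  0.3426
attr(f, "memory_cor")
#> [1] -0.899
```

Units that respond more strongly the higher the remembered F1 respond
more weakly the higher the current F2 and vice versa (negative
correlation between `a1` and `a2`): the memory layer has learned to
compute the difference between the stored and the sensed frequency, which
is exactly the quantity the task rewards.

## Command line

A thin front end over the same functions lives in `inst/cli/augmentrl.R`:

```sh
Rscript inst/cli/augmentrl.R train   --task saccade --n-networks 100 --out runs/s1
Rscript inst/cli/augmentrl.R train   --config run.cfg
Rscript inst/cli/augmentrl.R sweep   --task saccade --n-networks 10 --out runs/sweep
Rscript inst/cli/augmentrl.R analyze --task vibrotactile --n-networks 5 --out runs/an
```

Config files are plain `key = value` text, e.g.

```ini
[learning]
beta = 0.15
lambda = 0.20
[architecture]
n_memory = 4
[run]
task = saccade
seed = 1
n_networks = 100
max_trials = 25000
shaping = true
out = runs/s1
```

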