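---
title: "Modeling depression as dendritic spine loss in a TD-learning agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling depression as dendritic spine loss in a TD-learning agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesim)
library(dplyr)
```

## The model

Major depressive disorder is accompanied by a loss of dendritic spines — and
therefore synapses — in prefrontal and hippocampal circuits. `spinesim`
implements a computational account of that observation: a deep
temporal-difference (TD) learning agent whose value network is subjected to
*weight decay*, so that every connection weight shrinks toward zero on every
update, in proportion to its own strength. Strong connections degrade
fastest, which is the essential statistical signature of losing synapses at
random from multi-synapse connections.

The agent lives in a small 9 x 9 room. Each episode it starts at a fixed
pose and must reach a *required goal* at a fixed location (reward +10,
episode ends). *Optional goals* (reward +1 each) are scattered uniformly at
random every episode, and a *hazard* (reward -5, non-terminal, persistent)
sits directly in front of the start pose, so every agent accumulates
hazard experience throughout training. The agent picks one of three actions
per step — turn left, turn right, move forward — and sees only a 5 x 5
egocentric window, rotated so it faces "up", with itself at the
bottom-center: 4 cells ahead and 2 to each side. Each window cell is encoded
one-hot over 4 object channels (wall, optional goal, required goal, hazard),
giving the network's 100 binary inputs.

Action values come from a small network: 100 inputs, 10 tanh hidden units,
3 linear outputs. Learning is online one-step semi-gradient TD: after each
step the reward-prediction error

\[
\delta = r + \gamma \max_b V(s', b) - V(s, a)
\]

is computed (the bootstrap term is dropped when the episode ended at the
required goal), the gradient of \(\delta^2\) with respect to every weight is
taken with the target held constant, and each connection weight is updated
as

\[
w \leftarrow w - \alpha \frac{\partial \delta^2}{\partial w}
           - \alpha \lambda w .
\]

The second term is the simulated spine loss: at \(\lambda = 0\) the agent is
"healthy"; at \(\lambda > 0\) every connection decays toward zero at a rate
proportional to its strength. Biases are updated by the gradient term only —
they represent a neuron's intrinsic excitability, not a synapse, and
exempting them lets the model express the bias compensation that accompanies
heavy decay (see `bias_summary()`).

## Model variants

`variant_config()` builds the alternative depression accounts, each
differing from `healthy` in exactly one mechanism:

| variant | mechanism | override |
|---|---|---|
| `healthy` | none | \(\lambda = 0\) |
| `spine_loss` | synaptic loss | \(\lambda = 0.02\) |
| `reduced_rpe` | weak dopamine signal | \(\delta\) scaled by 0.1 |
| `dual_rate` | faster learning from bad outcomes | negative rewards x 2, positive / 2 |
| `high_discount` | steeper explicit discounting | \(\gamma = 0.5\) instead of 0.9 |
| `high_exploration` | exploration/exploitation imbalance | softmax policy, \(\tau = 1\) |
| `random_deletion` | random synapse pruning | half the connections zeroed and masked |

Scaling \(\delta\) by 0.1 is mathematically identical to using a learning
rate of \(\alpha/10\); the implementation scales \(\delta\) because that is
the dopaminergic interpretation. `random_deletion` uses exact-count sampling
(half of each weight matrix, exactly) and permanent masks, so deleted
connections can never be re-learned.

## Hyperparameters

* \(\alpha = 0.01\) — learning rate. Larger values (0.03+) destabilize
  learning in this room.
* \(\gamma = 0.9\) — explicit discount factor (0.5 in `high_discount`).
* \(\epsilon = 0.1\) — exploration rate of the epsilon-greedy policy.
* \(\lambda = 0.02\) — the spine-loss decay setting; `decay_sweep()` treats
  \(\lambda\) as the swept variable from 0 to 0.1.
* \(\tau = 1\) — softmax temperature, used by `high_exploration` and by the
  KL-divergence exploration comparison.
* Parameters initialize uniformly in \([-0.1, 0.1]\) from the run's seed.
* `max_steps_per_episode = 500` guarantees termination; converged healthy
  agents need ~40 steps per episode, spine-loss agents ~100.

Episode budgets: `run_comparison()` trains 20,000 episodes per agent, which
brings every variant to its behavioral asymptote — including `reduced_rpe`,
whose effective learning rate is a tenth of the others' and which
converges about ten times more slowly. Shorter budgets (3,000 episodes) make
under-trained variants look spuriously "depressed": an early network that
has not yet localized the hazard or learned the junction preference is
indistinguishable from one that lost that structure to decay. The default
desk scale is 5 repetitions per variant; figure-level claims in the source
literature used 20, available via the `reps` argument.

## The probe battery

All probes are read-only forward passes; no learning or decay occurs during
probing. The geometries are anchored to the default room (goal at (9,9)):

* **Anhedonia junction** (`probe_scenario("anhedonia_junction")`): the agent
  stands at (5,8) facing east with the required goal diagonally ahead-right
  and an optional goal on its right-adjacent cell. The detour (turn right,
  collect, turn left, continue) costs exactly one extra action, so at
  \(\gamma = 0.9\) it is reward-optimal:
  \(\gamma \cdot 1 + \gamma^6 \cdot 10 > \gamma^5 \cdot 10\). A model is
  classified anhedonic when a Welch two-sample t-test across repetitions
  finds *no* significant difference between \(V(\text{turn right})\) and
  \(V(\text{forward})\) — the loss of any preference about the bonus.
* **Discount inference** (`infer_discount()`): the agent is placed 1–4
  forward steps from the goal and the maximum action value recorded;
  ordinary least squares on \(\log V(d) = c + d \log \gamma_{\mathrm{eff}}\)
  yields the *effective* discount factor. Distances stop at 4 because from 5
  steps out the goal leaves the visual field and the view becomes identical
  to every deeper position (partial-observability aliasing), which would
  contaminate the fit with a constant-value plateau.
* **Hazard approach** (`avoidance_probe()`): a hazard guards the cell
  directly before the goal and the agent is placed at four successive
  positions walking into it. The goal enters the visual field from position
  2, so a network that localizes threat shows rising forward-value through
  positions 1–3 and a drop only at position 4 (where forward steps onto the
  hazard). Generalized avoidance is a significant *premature* drop
  (1 to 2 or 2 to 3, one-sided Welch test).
* **Exploration comparison** (`exploration_divergence()`): both networks'
  values are converted to softmax policies (\(\tau = 1\)) on 100 random
  reachable world states and the mean \(\mathrm{KL}(\text{healthy} \,\|\,
  \text{variant})\) compared, across repetitions, against the
  healthy-vs-healthy baseline (divergence between independently trained
  healthy agents).

`behavior_matrix()` reduces the battery to four flags per variant; it is a
pure function of the tidy per-repetition statistics table, so saved results
re-classify identically.

## Numerical and design choices

* Coordinates are 1-based `(col, row)`; headings rotate clockwise under
  `turn_right`; greedy ties break toward the lowest action index; all
  randomness flows through R's RNG, so `(seed, config)` determines every
  trajectory and parameter bit-for-bit.
* The training loop runs in C++ for speed; a pure-R engine
  (`train_agent(..., engine = "r")`) consumes the identical RNG draw
  sequence and is tested to agree to ~1e-12.
* Terminal (goal) transitions drop the bootstrap term; step-cap truncation
  keeps it, since the cap is a measurement artifact rather than a real
  terminal state.
* The update is applied as `w * (1 - alpha*lambda) - alpha*grad`, which
  makes the pure-decay trajectory exactly geometric,
  \(w_t = w_0 (1-\alpha\lambda)^t\).
* Welch two-sample t-tests at the 0.05 level implement every "significant
  difference" in the classification criteria; with zero-variance degenerate
  samples the flag falls back to the sign of the mean difference.
* `curve_metrics()` measures learning speed as the first episode whose
  rolling-window reward slope is within 5% of the final slope and stays
  there.

## What the synthetic world does and does not capture

The room is a minimal sequential-decision metaphor: optional goals stand for
discretionary rewarding activities, the required goal for obligatory
survival behavior, the hazard for aversive experience. The generator
reproduces the qualitative regime of the source model — converged healthy
agents collect almost two of the three bonus goals per episode while
spine-loss agents collect about one and still reach the required goal — but
it is not a fit to any behavioral dataset, and passing tests say nothing
about depression in humans; they say the *mechanistic claim* (weight decay
induces this phenotype battery in this task) is reproduced.

Two phenotype cells are known not to reproduce under this reconstruction,
and the test suite reports them honestly rather than papering over them:

* *Generalized avoidance in the spine-loss agent.* Here weight decay
  **erases** the hazard response (the value penalty for a hazard one step
  ahead shrinks from about -5.6 in healthy networks to about -0.2) rather
  than smearing it across distances. A premature value drop would require
  hazard features that are strong but poorly localized; no decay setting we
  examined produces that combination in this task, plausibly because the
  original's unpublished reward magnitudes and decay schedule sit in a
  different regime.
* *Exploration divergence of the high-discount model.* Its softmax policy
  matches the healthy policy almost everywhere (both are near-uniform far
  from the goal and peaked near it), so its KL divergence from healthy sits
  at the healthy-vs-healthy baseline.
* *The simplified task.* With the optional goals and hazards removed the
  spine-loss impairment should vanish; here it persists (final reward about
  7.6 versus the healthy 10.0 at convergence, with occasional seeds
  collapsing entirely). Removing the bonus rewards makes reward events
  *sparser*, so gradient refresh is rarer relative to the decay and the
  value function is harder, not easier, to sustain — the opposite regime
  from the original report, again pointing at unpublished parameter
  differences.
* *A beneficial amount of mild decay.* In `decay_sweep()` performance
  declines monotonically from `lambda = 0`; the regularization benefit of
  mild decay presumably requires a task with more overfitting pressure than
  this fully stationary room provides.

The spine-loss anhedonia classification is borderline at the 0.05 level at
the default decay setting: smaller \(\lambda\) strengthens it but weakens
the exploration divergence, and no single setting produces all four
phenotypes at once in this reconstruction.

## A worked run

```{r comparison, eval = FALSE}
# ~2 minutes: 6 variants x 5 repetitions x 20,000 episodes
cmp <- run_comparison(seed = 1)
cmp$behavior
autoplot(cmp$behavior)
```

```{r restoration, eval = FALSE}
res <- restoration_experiment(reps = 5, episodes_per_phase = 3000, seed = 1)
res$recovery
autoplot(res)
```

The restoration experiment switches \(\lambda\) from 0 to 0.02 and back
across three equal phases of continuous training: the reward rate drops
under decay, dips further briefly after restoration (the network must
re-learn through its recovering weights), then returns to the healthy
level.

A fast small-scale demonstration that runs in a few seconds:

```{r quick}
ag <- train_agent(world_config(), variant_config("spine_loss"),
                  episodes = 300, seed = 1)
glance(ag)
```
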