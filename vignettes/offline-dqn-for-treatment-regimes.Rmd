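---
title: "Offline deep Q-learning for dynamic treatment regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Offline deep Q-learning for dynamic treatment regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After an allogeneic hematopoietic cell transplant, patients are followed at
a handful of scheduled visits (transplant day, 100 days, 6 months, 1 year,
2 years). At each visit a clinician observes the patient's status — alive
and well, acute graft-versus-host disease (aGVHD), chronic GVHD (cGVHD),
relapse, or death — and chooses a treatment from a large set of drug
combinations. A *dynamic treatment regime* (DTR) is the sequence of
decision rules mapping the evolving state to a treatment at each stage.
`deepdtr` estimates an optimal DTR from logged registry trajectories by
offline deep Q-learning, and evaluates the learned policy off-policy.

Registry data are observational: we only see the treatments experts chose,
we can never execute a candidate policy on real patients, and the action
space (hundreds of drug combinations) is far too large for classical
tabular Q-learning or SMART-style DTR methods. These three constraints
shape the whole design: learning is purely offline (experience replay over
logged transitions), the value function is a neural network rather than a
table, and an expert-imitation network screens the action space down to
treatments clinicians would plausibly give, because value estimates for
never-taken actions are untrustworthy.

## The decision model

Time is discrete with stages $t = 0,\dots,4$ mapping to days
$\{0, 100, 180, 365, 730\}$. The state $s_t$ is an 8-vector: four status
indicators (alive, aGVHD, cGVHD, relapse) and four baseline-derived
features (age/100, sex, donor-relation category code, comorbidity count).
Actions $a_t$ are drug combinations, coded by a bijection between observed
drug sets and indices $1..K$. Death and relapse are terminal.

The reward earned on *arriving* in a state is a heuristic quality-of-life
score: 1 if alive and free of GVHD and relapse, 0.8 if alive with aGVHD,
0.7 if alive with cGVHD, 0 if dead. The target of estimation is the
optimal action-value function

$$Q^*(s, a) = \max_\pi \mathbb{E}\Big[\sum_{k=t}^{T} \gamma^{\,k-t} r_k
\,\Big|\, s_t = s, a_t = a, \pi\Big], \qquad \gamma = 0.99 .$$

Two conventions are not fixed by the reward's four cases and are package
design choices, both configurable in `immediate_reward()`:

* a patient with **both** GVHD forms scores 0.7 — the worse condition
  dominates a quality-of-life proxy;
* **relapse**, though the patient may be alive, is absorbing and scores 0,
  i.e. it is treated as failure like death.

## Offline Q-learning

`train_dqn()` is the package's central fitting function. The Q-network is
a fully connected ReLU network (default $8 \to 32 \to 64 \to K$). Logged
transitions $(s_t, a_t, r_t, s_{t+1})$ are loaded into a bounded FIFO
replay buffer (capacity 20 000; beyond that the oldest tuples are
discarded). Training then iterates: sample a uniform mini-batch of 256
tuples from the buffer, form temporal-difference targets

$$y_i = \begin{cases} r_i & \text{episode end} \\
r_i + \gamma \max_{a'} \hat Q(s'_i, a'; \theta') & \text{otherwise,}
\end{cases}$$

take one Adam step (learning rate $10^{-3}$) on the squared TD error of
the taken actions, and softly track the target network,
$\theta' \leftarrow \tau\theta + (1-\tau)\theta'$ with $\tau = 0.01$. The
target network starts as an exact copy of the Q-network; the slow tracking
stabilizes the bootstrap targets.

There is no $\varepsilon$-greedy exploration anywhere: the data are fixed
logs, so the action-selection part of Q-learning is exercised only at
recommendation time (`recommend()`, greedy over an admissible set, ties to
the lower index).

**Episode-end convention.** The state carries no stage index, so a network
bootstrapping through an end-of-follow-up arrival would chase the
*stationary* fixed point of the chain, inflating all values by an order of
magnitude. Follow-up ends for a reason: patients alive and relapse-free at
the final visit are considered cured. `to_transitions()` therefore flags
arrival at the final stage (default stage 4) as an episode end alongside
death and relapse; the arrival reward is still collected, but no value is
bootstrapped past it. With this convention the learned values stay on the
finite-horizon scale (at most $\sum_{k=0}^{3} 0.99^k \approx 3.94$ plus
approximation error).

**Stabilizing offline TD learning.** Off-policy bootstrapping with a
function approximator is prone to an overestimation spiral: the network
partially memorizes per-patient noise (the baseline features are
continuous and patient-specific), and the $\max_{a'}$ operator converts
that estimation noise into a systematic upward bias that feeds back
through the targets. Two defaults counteract it, both tunable in
`dtr_hyper()`: a large TD mini-batch (256; averaging the bootstrap noise
within each Adam step rather than chasing it) and a mild L2 weight decay
($10^{-3}$) that limits memorization of the nuisance inputs. The
supervised networks keep the conventional batch of 32 and no decay —
their losses have no bootstrap feedback. The test suite checks the
resulting value scale: learned maximum Q-values on visited states stay
near the discounted-horizon bound instead of drifting above it.

**Epochs and stopping.** One epoch is one pass of
$\lceil n/\text{batch}\rceil$ mini-batch steps over an $n$-transition
dataset; the default budget is 100 epochs. Because the TD loss first
*rises* while the bootstrapped values warm up, plateau detection compares
the mean loss of the two most recent 15-epoch windows rather than a global
best, stopping only when they agree to within 1% (flatness, not
non-improvement), and never before two full windows.

Separate models are intended per condition: aGVHD treatment uses decision
stages 1–2, cGVHD stages 1–4 (the `stage_filter` argument); initial
conditioning and GVHD prophylaxis are stage-0 decisions predicted by the
supervised networks with a 9th input (the stage index).

## Expert screening and the supervised networks

`train_expert_predictor()` fits a softmax cross-entropy classifier
(default $8 \to 16 \to 32 \to K$, Adam at $10^{-4}$) that imitates the
logged expert actions. Its `screen_actions()` top-$N$ sets restrict DQN
recommendations to plausible treatments; `top_n_accuracy()` is the
corresponding screening accuracy (monotone in $N$, 1 at $N = K$; ties rank
the lower index first). The loss and output layer are package choices —
the probability semantics of screening requires a softmax, and
cross-entropy is the standard imitation loss. Default supervised training
runs up to 200 epochs, batch 32, with early stopping on a 10% validation
split (patience 20).

All networks share a small hand-written MLP engine (Glorot-uniform
initialization, ReLU hidden layers, linear output, backpropagation, Adam).
Writing the engine in base R keeps every gradient step inspectable and the
whole pipeline dependency-light; its gradients are verified against finite
differences in the test suite.

## Evaluation protocols

Two off-policy estimates are implemented, mirroring how such policies must
be judged when counterfactual outcomes are unobservable:

* **Matched reward** (`matched_reward()`): over the held-out 20% of
  patients (split at the patient level to prevent leakage), average the
  next-state arrival reward over the stage records where the expert's
  logged action equals the policy's recommendation. Matching is per stage
  record by default — whole-trajectory matching is configurable but yields
  vanishing match counts when $K$ is large. Uncertainty comes from a
  percentile bootstrap of the matched rewards (`bootstrap_ci()`, 5 000
  resamples by default). A policy recommending only unobserved actions
  raises an explicit "no matched patients" error rather than returning 0.
* **Counterfactual value** (`counterfactual_value()`): a separately
  trained reward network (`train_reward_predictor()`, squared error, Adam
  at $10^{-4}$, predictions clipped to $[0,1]$) maps (state, one-hot
  action) to the immediate reward; the policy's value is the mean
  prediction at its recommended actions, compared against
  `baseline_excluding_top()`, the mean prediction over all *other*
  actions.

Comparison baselines: the one-size-fits-all policy (modal observed
treatment, `one_size_fits_all_policy()`), a random-forest reward
regression with greedy argmax (`random_forest_policy()`, via the
randomForest package — the forest's target is a package choice, as a
one-step fitted-value analogue), a uniform-random policy, and the
observed expert actions themselves.

## The synthetic registry and its oracle

Real transplant-registry cohorts are restricted, so the package ships a
simulator (`simulate_cohort()`) that emulates the registry's *structure*:
heterogeneous stages, terminal death/relapse, drug-set actions from a
finite observed space, and a stochastic state-dependent expert. The
ground truth is a Markov decision process on the observable clinical
status — by construction the encoded state is Markov-sufficient, which
makes the DQN's Markov assumption true in tests (real disease progression
is not exactly Markov; see Limitations).

The default scenario, fixed once as the package's study condition:
2 000 patients, 4 drug combinations over 3 drugs, 4 post-baseline stages,
all patients healthy at day 0. Each transient status (healthy, aGVHD,
cGVHD) has a different strictly dominant combination, with one-step
expected-reward gaps of roughly 0.07–0.15 — large enough that the optimal
policy is identifiable from a cohort of this size, small enough that the
behavior policy's preferences do not give the answer away. The expert
behavior policy is a softmax over $3\times$ the one-step expected reward
(temperature 1), so experts are better than random but every action keeps
support — a requirement for offline learning. Baseline features are
sampled from registry-realistic distributions (age truncated normal
40 ± 15; donor-relation categories at the HLA-matching frequencies typical
of large transplant registries, about 64/7/11/7/3/7%); they influence
nothing in the dynamics, so they act as realistic nuisance inputs the
networks must learn to ignore.

Because the latent chain is known, two exact quantities anchor every test:
`optimal_policy_oracle()` solves the finite-horizon MDP by backward
induction, and `policy_value_exact()` propagates the status distribution
forward to value any policy without simulation noise. The test suite
verifies the oracle against brute-force enumeration of all deterministic
policies on a reduced two-state problem, and verifies the forward
propagation against an independent recursive evaluator and Monte-Carlo
simulation.

What passing tests on this simulator do **not** show: that the method
recovers optimal regimes on real registry data. Real cohorts have
covariate-dependent and non-Markov dynamics, informative censoring,
hundreds of actions with very uneven support, and measurement error in
the status forms. The simulator establishes correctness of the machinery
(the estimation pipeline recovers a known truth under its own
assumptions), not clinical validity.

## Numerical choices and degenerate inputs

* Randomness: every stochastic routine takes a seed and is exactly
  reproducible; the same seed gives byte-identical cohorts, weights and
  intervals.
* Ties: all argmax operations (recommendation, screening ranks, modal
  action, oracle) break toward the lower action index, so results are
  deterministic.
* Reward-model predictions are clipped to $[0, 1]$; rewards outside that
  range are rejected at construction.
* Degenerate inputs error early and loudly: empty transition sets, empty
  admissible sets, unknown drug sets (named in the message), unknown
  baseline categories (field named), zero matched patients, non-finite
  training loss.
* A constant-reward cohort makes the random-forest baseline a constant
  policy rather than an error.
* The low-variance filter drops exactly the columns whose sample variance
  is at or below the threshold (default 0: constants only), preserving
  column order.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full pipeline at the
default study condition (2 000 patients, ≈ 5 500 transitions, 100-epoch
budget with plateau stopping); smaller MDPs (2 actions, horizons 2–3,
60–400 patients) exercise the oracle equivalences, and bootstrap coverage
uses 500 replicates of 400 observations at 2 000 resamples each. These
sizes were chosen so each property is measured with comfortable
statistical margin while a full run stays in the minutes range on a
single core.

## Limitations

* The Q-network sees no stage index, so the learned rule is shared across
  stages; on the default scenario the optimal action happens to be
  stage-invariant, which this choice exploits. A stage-aware state schema
  is one `state_schema()` away but is not the default.
* Offline Q-learning has no convergence guarantee with function
  approximation, and none of the estimators corrects for confounding
  beyond what the state captures; matched-reward estimates are biased
  when matching correlates with prognosis.
* Double-DQN, prioritized replay, importance-sampling and doubly robust
  off-policy estimators are out of scope, as are recurrent
  (history-dependent) models.
* The simulator's transitions depend only on the clinical status, not on
  baseline covariates; a covariate-dependent extension would need a
  different oracle.
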