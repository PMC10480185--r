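---
title: "Bounded-confidence opinion dynamics with algorithmic bias and mass media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-confidence opinion dynamics with algorithmic bias and mass media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionmedia)
```

## The model

`opinionmedia` simulates a population of $N$ agents holding continuous
opinions $x_i \in [0,1]$, where 0 and 1 are the two most extreme stances on
an issue. Three mechanisms drive the dynamics:

**Bounded confidence (cognitive bias).** When agents $i$ and $j$ interact
and their opinions differ by at most the confidence bound $\varepsilon$,
both move a fraction $\mu$ of the gap towards each other:

$$x_i \leftarrow x_i + \mu\,(x_j - x_i), \qquad
  x_j \leftarrow x_j + \mu\,(x_i - x_j),
  \qquad \text{iff } |x_i - x_j| \le \varepsilon .$$

With $\mu = 0.5$ (the default) both adopt the pair mean, and the population
opinion sum is conserved by every accepted media-free update. A low
$\varepsilon$ describes a close-minded population; a high $\varepsilon$ an
open-minded one.

**Algorithmic bias (recommender filtering).** The interaction partner is
not chosen uniformly. After a target agent $i$ is picked uniformly at
random, its peer $j$ is drawn with probability

$$p_i(j) = \frac{d_{ij}^{-\gamma}}{\sum_{k \ne i} d_{ik}^{-\gamma}},
  \qquad d_{ij} = |x_i - x_j|,$$

so the filtering exponent $\gamma \ge 0$ concentrates interactions on
like-minded peers; $\gamma = 0$ recovers uniform (Deffuant–Weisbuch)
partner choice. Distances are clamped below at `distance_floor`
($10^{-4}$ by default) so coincident opinions keep a finite weight.

**Stubborn mass media.** An arbitrary number $M$ of media outlets hold
fixed opinions. After each peer interaction, with probability $p_m$ the
target agent also consults one medium — selected with the same biased
kernel over media opinions — and moves towards it by the bounded-confidence
rule if the medium lies within the agent's bound. Media never move. With
$p_m = 0$ or $M = 0$ each step is exactly one step of the media-free
algorithmic-bias model.

One *iteration* of the simulation is one such pair event (plus the possible
media event); it is not a sweep over all agents. This keeps the default
iteration cap of $10^6$ meaningful for $N = 100$.

### Heterogeneous confidence bounds

For network case studies each agent can carry its own bound
$\varepsilon_i$. The update is then gated per side on the pre-update
opinions — $i$ moves to the pair average iff $d_{ij} < \varepsilon_i$, $j$
iff $d_{ij} < \varepsilon_j$ — so one-sided persuasion is possible. Note
the deliberate asymmetry at exact equality: the homogeneous gate is
inclusive ($\le \varepsilon$), the heterogeneous gate strict
($< \varepsilon_i$). Both forms are kept as commonly written rather than
reconciled; the discrepancy only matters on a measure-zero set of states,
but the package documents it instead of silently picking one convention.

## Parameters at a glance

| Parameter | Meaning | Range | Default |
|---|---|---|---|
| `epsilon` | confidence bound (scalar or per-agent) | $[0,1]$ | — |
| `gamma` | algorithmic-bias exponent | $\ge 0$ | 0 |
| `mu` | convergence parameter (gap fraction closed) | $(0, 0.5]$ | 0.5 |
| `p_m` | per-step media-consultation probability | $[0,1]$ | 0 |
| `distance_floor` | lower clamp on kernel distances | $> 0$ | $10^{-4}$ |
| `max_iterations` | iteration cap | $\ge 0$ | $10^6$ |

All quantities are unitless; opinions and bounds live on the opinion scale
itself.

## Stopping rules and their calibration

Two stopping rules are provided (`stopping_rule()`):

* **Cluster equilibrium** (mean-field default): the gap-threshold cluster
  partition (gap 0.01) is recomputed every 1,000 steps; the run stops when
  100 consecutive checks see the identical partition — the population may
  keep exchanging opinions inside clusters, but the cluster configuration
  no longer changes. The 100-check patience is a deliberate calibration:
  with a short window (e.g. 10 checks) strongly biased runs
  ($\gamma = 1.5$) are regularly declared converged while their partition
  still changes tens of thousands of steps later, because the biased
  kernel makes between-cluster events rare rather than impossible. A
  100,000-step unchanged window reproduced the configuration found at the
  full $10^6$ cap in every validation probe we ran; the stride and
  patience remain configurable.
* **Maximum-change** (network case-study default): stop once the per-step
  maximum absolute opinion change stays below 0.01 for 500 consecutive
  steps, with a cap of $10^5$ iterations.

Runs that reach the cap are reported with `converged = FALSE` and
`stop_reason = "iteration_cap"` — under a balanced media landscape and
high openness this is an expected outcome, not an error, since agents keep
being pulled between media and a true equilibrium need not exist.

## Randomness and replay

All randomness flows through R's generator: seed once (or set
`model_config(seed = )`) and a run is bit-reproducible. Each step consumes
draws in a fixed order — target pick, peer pick (cumulative-sum inversion
over the kernel weights), then, only when media are active, the media gate
and the media pick. The compiled driver and the pure-R
`simulation_step()` consume the stream identically, which the test suite
exploits for seed-matched cross-checks against an independently written
naive Deffuant–Weisbuch implementation.

## Measures of the final state

* `detect_clusters()` sorts final opinions and opens a new cluster when a
  consecutive gap strictly exceeds 0.01 (a gap exactly at the threshold
  does not split). Singletons count; `n_major_clusters()` additionally
  reports clusters holding at least 2% of the population, since stray
  frozen singletons otherwise dominate the count.
* `participation_ratio()` computes
  $C = (\sum_i c_i)^2 / \sum_i c_i^2$, an effective number of equally
  sized clusters in $[1, n]$.
* `media_cluster_occupancy()` reports the percentage of agents inside the
  closed band $[x_m - \lambda, x_m + \lambda]$, $\lambda = 0.01$.
* `peak_pairwise_distance()` averages distances between cluster mean
  opinions (the peaks); an all-agent-pairs variant is available via
  `peaks = FALSE` since usage of the phrase varies.
* `opinion_entropy()` is Shannon entropy (base 2) of a 100-bin histogram;
  base and bin count are artifact conventions, stated here because no
  standard exists.
* `echo_chamber_stats()` pairs every non-isolated node's opinion with its
  neighbours' mean opinion and reports their joint histogram and linear
  correlation — the echo-chamber diagnostic. The correlation is flagged
  undefined when either marginal is degenerate (e.g. after consensus).

## Synthetic inputs

The generators define the study conditions rather than serving as mere
test props:

* `uniform_initial_opinions()` draws the standard mean-field initial
  condition, i.i.d. uniform on $[0,1]$, population 100.
* `scenario_media()` returns the four landscapes analysed in the
  mean-field experiments: moderate (0.5), extremist (0.0), polarized
  (0.05, 0.95) and balanced (0.05, 0.5, 0.95) — adjacent balanced media
  are 0.45 apart, which interacts with $\varepsilon = 0.4$ populations in
  an instability band.
* `polarized_network()` emulates a polarized online-discussion snapshot:
  a two-block stochastic block model with equal communities, opinions
  drawn truncated-normal (spread 0.1 by default, chosen to produce
  visibly separated factions) around faction means 0.28 and 0.87 — the
  pro/against faction averages also used by `casestudy_media()`. It is a
  stand-in, not a reconstruction: real snapshots additionally have
  scale-free degrees, a giant component with tendrils, and correlated
  $\varepsilon_i$; passing tests on the fixture therefore demonstrate
  mechanism correctness, not empirical fidelity.
* `heterogeneous_epsilon_assignment()` draws per-agent bounds from a
  described distribution (constant, uniform or beta on $[0,1]$), standing
  in for bounds estimated from data; the estimation procedure itself is
  out of scope and per-agent bounds are accepted as input.
* `synthetic_annotations()` fabricates a hashtag annotation table with a
  configurable pro/neutral/against mix for exercising the leaning
  pipeline end-to-end.

## The leaning pipeline

`user_leanings()` maps an annotation table (tweet, user, hashtag, score in
$\{-3,-1,0,+1,+3\}$) to model opinions: per-tweet mean of non-neutral
scores, per-user mean of defined tweet scores $C_u \in [-3,3]$, linear
normalization $(C_u+3)/6$ to $[0,1]$, then discretization into Pro
($\le 0.4$), Against ($\ge 0.6$) and Neutral. The thresholds are applied
on the normalized scale — the only reading under which the three bands
partition $[0,1]$ — and tweets with only neutral hashtags, and users with
no scorable tweets, are excluded (the latter counted in an attribute).
`faction_media_opinions()` turns faction means into a media landscape.

## Numerical choices and degenerate inputs

* Weighted picks invert a plain-double cumulative sum; ties at the cut
  point resolve to the earlier candidate, and the last candidate absorbs
  terminal rounding.
* Self-selection is impossible: the kernel normalizes over $k \ne i$.
* The media pick consumes its gate draw only when `p_m > 0` and
  $M \ge 1$, so media-free runs replay the two-draw-per-step baseline
  exactly.
* A medium outside the agent's bound can still be selected — bias governs
  which medium is approached, the bound whether it persuades — so a
  "wasted" media event is a modelled outcome.
* `max_iterations = 0` returns the initial state under
  `stop_reason = "iteration_cap"`; an agent without neighbours raises an
  error naming the node; an edgeless graph is rejected by the
  echo-chamber statistics.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script replicate ensemble results at
desk scale: 100 agents, 10–20 replicates per condition, the
cluster-equilibrium rule with cap $10^6$. At these sizes the headline
regimes are stable: close-minded media-free populations polarize into two
main camps near 0.25 and 0.75 (commonly rounded to 0.2/0.8 in the
literature); open-minded ones reach consensus at the conserved mean 0.5;
a single extremist medium at 0.0 with $p_m = 0.5$ fragments a
close-minded population into about three main clusters. One caveat is
documented rather than hidden: under the balanced landscape with strong
bias ($\gamma = 1.5$) the simulated mean main-cluster count is about 4.4,
not $\le 3$ — besides the three media-anchored clusters, 2–5-agent
satellites freeze near 0.25 and 0.75, provably unreachable (farther than
$\varepsilon$ from every large cluster and every medium), so longer runs
cannot merge them. Satellite formation is kinetic and sensitive to the
event semantics; with the one-pair-per-step semantics implemented here
the satellites are a robust outcome, and the corresponding acceptance
test is allowed to fail rather than being loosened.

## Known limitations

* Mean-field ensembles describe a fully mixed population; network
  structure, degree heterogeneity and community structure change
  outcomes, and the network mode performs single runs per scenario as a
  case-study tool, not an ensemble machine.
* Media are global: every agent can consult every outlet. Follower
  structure, media adaptation and repulsive (backfire) updates are out of
  scope.
* The per-agent bound estimation from longitudinal data is out of scope;
  heterogeneous runs take $\varepsilon_i$ as given.

## A minimal session

```r
library(opinionmedia)

set.seed(1)
x0  <- uniform_initial_opinions(100)
cfg <- model_config(epsilon = 0.2, gamma = 0, mu = 0.5, p_m = 0.5)
res <- run_model(x0, mean_field_graph(100),
                 scenario_media("extremist"), cfg)

summarize_run(res, scenario_media("extremist"))
```
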