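---
title: "Modelling friend and foe designation in small groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling friend and foe designation in small groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

amity simulates how the members of a small closed group — the motivating
case is a school class of 25–30 students — come to regard each other as
friends or enemies, and how those relations surface in a sociometric
survey. The package has two stages: a dynamical stage in which opinions
and signed link weights co-evolve, and a designation stage that converts
the final state into a directed friend/foe mention network under a
specific survey protocol. This vignette describes both stages, the
choices we made where the design was genuinely open, and what the
synthetic fixtures do and do not emulate.

## The opinion dynamics

Each agent $i$ carries a private opinion $x_i \in [-1, 1]$ that nobody
else observes, a public (apparent) opinion $y_i \in [-1, 1]$, and a
fixed crowd attitude $\alpha_i \in [-1, 1]$: positive $\alpha$ follows
the aggregated public information, negative $\alpha$ opposes it. Agents
sit on a signed network whose symmetric weight matrix $A$ starts as a
random graph with mean degree $\langle k \rangle$ and all weights equal
to 1 — initially nobody is an enemy.

What an agent shows a neighbour is a blend controlled by the openness
$\tau \in [0, 1]$:

$$w_{ij} = \tau\, x_i(t-1) + (1 - \tau)\, y_j(t-1),$$

so at $\tau = 1$ agents broadcast their private state and at $\tau = 0$
they merely echo the other's public face. The public opinion is the
degree-normalised mean of the signals an agent emits, and the private
opinion obeys

$$\dot x_i = f_s(i)\,|x_i| + \alpha_i f_l(i),$$

where the short-range field $f_s(i)$ sums the signals arriving from
first neighbours and the long-range field
$f_l(i) = \sum_{\ell \ge 2} \sum_{j : d(i,j) = \ell} y_j / \ell$
aggregates the public opinions of everybody else, damped linearly with
hop distance. The factor $|x_i|$ makes the local interaction homophilic:
it pushes $x_i$ in the direction of the consensus among its neighbours.

Link weights grow or decay with the pair kernel

$$T_{ij} = \left|\tfrac{x_i + x_j}{2} + 3\,\tfrac{y_i + y_j}{2}\right| - 1,
\qquad \dot A_{ij} = D\, T_{ij},$$

which ranges over $[-1, 3]$: public and private agreement strengthens a
bond, opposed opinions erode it until the weight turns negative — an
enemy link. Every `rewire_interval` iterations the network is inspected:
each link that turned negative since the last check is answered by one
fresh link of weight 1 placed between a currently unlinked pair,
preferring the pair with the smallest degree sum (ties broken at
random). Negative links are never removed; the persistent ones mark the
real enemies.

### Numerical scheme and conventions

* **Integration.** Plain synchronous Euler with step `dt = 0.002`:
  disclosures, public opinions and both fields are evaluated at
  $t - 1$, then $x$, then the kernel and $A$. The kernel is evaluated
  once per unordered pair, so $A$ stays numerically symmetric to the
  last bit.
* **Clipping.** $x$ is clipped to $[-1, 1]$ after each step. The
  dynamics have no intrinsic bound on $x$ (the drive grows with
  degree), and the saturated states $x = \pm 1$ are exactly the locked
  extremes the model is meant to produce; $y$ is a convex combination
  of bounded quantities and stays inside the interval on its own.
* **Orientation of $W$.** The defining equations can be read with $W$
  indexed either way (what $i$ emits vs what $i$ receives). We adopt:
  $w_{ij}$ is what $i$ gives to $j$; $y_i$ is the mean of row $i$ (the
  face $i$ shows, averaged over its neighbours); $f_s(i)$ sums the
  incoming column. The alternative reading is available as
  `y_convention = "column"` in `model_params()` so both interpretations
  can be exercised and compared.
* **Distances.** Hop distances for the long-range field are counted on
  the unweighted skeleton of all nonzero-weight links — hostile links
  still carry information. Zero-weight entries behave as absent links.
  By default every reachable shell at distance $\ge 2$ contributes
  (`l_max = "diameter"`); a fixed cut-off is available.
* **Free constants.** The link-growth scale is `D = 1` and the default
  run length is `n_steps = 5000` (10 time units), long enough for a
  25-agent group to saturate opinions and accumulate a stable set of
  negative bonds; both are configuration fields, not hard-coded.
* **Degenerate inputs.** Isolated agents keep their previous public
  opinion and feel no fields; a divergence guard aborts on non-finite
  states rather than propagating them.

## Fitness and homophily

Who gets *named* a friend depends on more than bond strength: standing
in the group matters. Each agent receives a fitness score, the weighted
mean of four normalised single-agent indicators — betweenness
centrality (divided by its combinatorial maximum $(n-1)(n-2)/2$), local
clustering, degree over $n - 1$, and the absolute signed bond sum
$|\sum_j A_{ij}|$ scaled by the cohort maximum. The default weights are
equal (each $1/4$); setting a weight to zero reproduces the ablations
over indicator subsets. The first three indicators are computed on the
skeleton of positive-weight links, which is the friendly "acquaintance"
structure; strength deliberately uses the full signed matrix so that a
agent with strong but cancelling bonds scores low. Normalising strength
by the cohort maximum (rather than per agent) keeps the score
comparable within a class; it is the one normalisation the defining
formula leaves open, and it is exposed as a choice rather than buried.

The homophily distance $\Delta_f(i,j) = |fit(i) - fit(j)|$ is a
pseudometric; its smallest values mark the most similar pairs.

## The two survey protocols

**Fixed quota ("name exactly q friends and q foes").** Each agent's
foes are its negative bonds, most negative first, truncated at $q$;
when fewer than $q$ negative bonds exist the list is completed with the
classmates of *largest* homophily distance. Friends are the $q$
classmates of smallest $\Delta_f$ among those not already listed as
foes. The friend-vs-foe asymmetry is deliberate: friendship tracks
similarity and standing, enmity tracks concrete negative interactions.
When one classmate qualifies under both headings the foe designation
wins, for the same reason; this also keeps the two lists disjoint,
which requires $2q \le n - 1$.

**Personal threshold ("rank everybody; we keep the extremes").**
Thresholds $\beta_1$ (on $\Delta_f$, friends) and $\beta_2$ (on
$A_{ij}$, foes) are calibrated once on an ensemble of finished runs
(default 40): $\beta_1$ is the 12th percentile of all pooled
upper-triangle $\Delta_f$ values, $\beta_2$ the 30th percentile of all
pooled final link weights. Percentiles interpolate order statistics
linearly (`stats::quantile()` type 7), so percentile 30 of the pool
$\{1, \dots, 10\}$ is 3.7. Each respondent then applies personal
cutoffs $\beta_{1,2} + \epsilon_i$ with a single noise draw
$\epsilon_i \sim U(-0.5, 0.5)$ shared by both thresholds — individual
strictness, not two independent moods. Foe designation requires an
existing bond below the cutoff; out-degrees vary and may be zero.

The `beta2_pool = "negative_only"` calibration option restricts the
$\beta_2$ pool to hostile links. Pooling all weights makes the nominal
"30th percentile" fall among weak-positive bonds and yields dense foe
nominations; the hostile-only pool reproduces the strongly
zero-inflated regime in which roughly half the group never receives a
foe mention, the signature of free-choice surveys.

## Summary statistics

The survey response variable is the number of mentions each agent
*receives*, per type. `survey_summary()` reports per-agent in-counts,
their cumulative distribution (relative accumulated frequency, a
right-continuous step table ending at 1), reciprocity (fraction of
edges sitting in a same-type mutual dyad), the zero-mention fraction
and the maximum. Ensembles are pooled by concatenating per-agent counts
across runs *before* forming the distribution, matching how data from
many classrooms are pooled. Distributions are compared with the
Kolmogorov–Smirnov statistic evaluated on the merged support of the two
step functions, with no continuity correction — a quantitative
stand-in for overlaying two empirical CDFs.

Two robust qualitative contrasts emerge and are asserted as stochastic
test properties (20 seeds at the default conditions): friend mention
networks are much more clustered than foe mention networks, and neither
type of mention is fully reciprocal.

## Synthetic fixtures

`generate_fixture()` produces mention networks of a prescribed shape
without running the dynamics, so the statistics layer is testable in
isolation. Quota-style fixtures give every agent exact out-degrees;
threshold-style fixtures draw Poisson out-degrees (defaults: mean 4.7
friend and 1 foe nomination, the free-choice regime) and can pin the
fraction of agents with no foe mentions and the per-type reciprocity
(local-search repair, within 0.05 of the target where feasible). When a
zero-foe fraction is requested, coverage of the remaining agents takes
precedence over the exact Poisson shape of the out-degrees: a few
sources may be assigned one extra nomination so that no agent is
*accidentally* foe-free. Fixtures emulate the degree structure,
reciprocity and zero-inflation of survey data — not homophily,
community structure, gender segregation, or any correlation between
friend and foe choices, so tests passing on fixtures say nothing about
those features of real classrooms.

## Problem sizes

The test suite integrates 20 full runs at the default conditions
(25 agents, $\langle k \rangle = 6$, $\tau = 0.8$, 5000 Euler steps)
for the bound, conservation and contrast properties, plus many short
runs and brute-force cross-checks on graphs of up to 8 nodes; the
acceptance script uses a 40-run ensemble for threshold calibration and
20 designation seeds per protocol. A single default run takes about
1.5 s; the entire suite stays around a minute.

## Known limitations

* The link dynamics are symmetric by construction; directionality lives
  entirely in the disclosure matrix and the mention networks.
* Only the two extreme survey categories (friend / foe) are modelled,
  not graded rankings.
* Model–data closeness for real surveys is descriptive (CDF overlays,
  KS distances); the package performs no significance testing.
* With `l_max = "diameter"` the long-range field scales with group
  size; comparisons across very different $n$ should fix `l_max`.
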