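---
title: "An absorbing Markov pathway model of pest arrival through container shipping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An absorbing Markov pathway model of pest arrival through container shipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestPathways)
```

## The problem

A hitchhiking organism — the motivating case is the khapra beetle
(*Trogoderma granarium*), a stored-grain pest whose diapause lets it sit
undetected in a shipping container for months — can board a container at any
port a vessel calls at, not just the last port of loading. Border agencies
that profile container risk by the immediate origin therefore miss most of
the pathway. Given route histories of container vessels arriving at a
destination country (here, the destination-country ports are called
*domestic*), this package estimates, for every foreign port and country
inside the organism's established range, the rate at which the organism
would arrive at each domestic port, and ranks ports and countries by that
rate.

## The model

**Route decomposition.** A voyage calling at ports A–B–C–D can move an
infested container over every ordered pair of calls: AB, AC, AD, BC, BD, CD.
Every voyage is decomposed into its set of unique ordered segments, and
$m_{ij}$ counts the vessels whose route covers segment $(i, j)$. A voyage
contributes at most once to a given $m_{ij}$: the counts are numbers of
vessels, not of call-position pairs (the positional count is available as an
option for comparison). The node set is the set of ports observed on routes.

**Transmission matrix.** The one-step transmission rate is the linear
rescaling $p_{ij} = \lambda_t\, m_{ij}$, with one scaling coefficient
$\lambda_t$ for the whole pooled survey period. Because only the *relative*
ordering of arrival rates is interpretable (the per-vessel transmission rate
is unknown), $\lambda_t$ only has to make every row sum admissible as a
probability: $\sum_j p_{ij} < 1$. The package sets
$\lambda_t = c / \max_i \sum_j m_{ij}$ so the largest row sum equals the cap
$c$ (default 0.9), which keeps absorption strictly positive everywhere and
makes runs reproducible. Rescaling $c$ multiplies every $p_{ij}$ linearly and
provably cannot change the ranking (a property the tests assert). The
diagonal is zero, and an absorption column
$p_{i,Y+1} = 1 - \sum_j p_{ij}$ represents the organism failing to survive
transit onward from port $i$; ports with no outgoing traffic absorb with
probability 1.

**Pathway simulation.** From each origin port inside the organism's range,
$K$ independent walks step through the matrix — at each port the next state
is drawn from that row's categorical distribution over destinations plus the
terminal state — until absorption, a port with no outgoing paths, or a hard
step cap. The arrival-rate estimate is $\hat\varphi_{ij} = J_{ij}/K$ where
$J_{ij}$ counts walks from $i$ that reached $j$. By default a walk counts at
most once per destination ("first visit"), so $\varphi_{ij} \le 1$ is the
per-pathway arrival probability; raw visit counting is available
(`countMode = "visits"`) since the published description does not fully pin
down the convention. The study-scale default is $K = 2 \times 10^6$ per
origin; the examples and tests use $10^4$–$10^5$, which the binomial error
bars in the next section make honest.

**Exact oracle.** The quantity the simulation estimates has a closed form:
the probability of ever visiting $j$ before absorption solves
$h_i = p_{ij} + \sum_{k \ne j} p_{ik} h_k$, non-singular because every row
sum is below 1. `visitProbability()` solves this per destination;
`visitProbabilityMatrix()` computes all pairs at once from the fundamental
matrix $N = (I - P)^{-1}$ via $h_{ij} = N_{ij}/N_{jj}$. The oracle is used
throughout the tests: Monte-Carlo cells must sit within
$4\sqrt{h(1-h)/K}$ of it, and the oracle itself is cross-checked against
truncated path enumeration (depth 20, geometric tail bound) on fixtures
whose row sums make the tail below $10^{-9}$.

**Aggregation.** The overall rate at a domestic port combines the
per-origin rates as the complementary product
$\Phi_j = 1 - \prod_i (1 - \varphi_{ij})$ — the probability that at least
one source delivers, assuming independent pathways. This choice is forced by
arithmetic: published per-origin rates for a single destination already
*sum* above the published overall rate (so a raw sum is out), while a raw
product would be orders of magnitude too small; the complementary product
reproduces the published overall rates as tight lower bounds when applied to
the truncated published top-ten lists (the package's check suite and
acceptance targets recompute exactly this). Foreign ports aggregate
symmetrically across domestic destinations, and countries aggregate their
ports' combined rates with the same rule. Relative rates divide by the mean
rate over the full entity set of the ranking in question, so they average
to 1; the per-destination breakdown tables share a single mean over all
origin–destination pairs, matching the published panels' convention.

## Sensitivity analysis

Three uncertainty scenarios perturb the matrix:

* **multiplicative** — each positive $p_{ij}$ is redrawn uniformly from
  $[p_{ij}(1-b),\, p_{ij}(1+b)]$ (default $b = 0.3$), mean-preserving and
  support-preserving: measurement error in rates, network structure known;
* **additive** — every off-diagonal entry, including zeros, gains a uniform
  variate on $[0, 0.05]$: loss of knowledge about where ships travel; the
  support becomes complete and the network drifts toward uniformity;
* **removal** — a fraction $f \sim U[0, 0.3]$ of the positive entries is
  deleted: uncertainty about the presence of individual paths.

Because literal additive noise across ~550 columns pushes row sums far above
1, perturbed rows are re-closed: a row whose sum exceeds a cap (default
0.99) is rescaled to it and absorption takes the complement. Rescaling
preserves within-row relative structure, which is what the rankings consume;
a `clip` policy that touches only genuinely inadmissible rows is provided.

Stability is summarized by ordinary least squares of perturbed rank on
baseline rank (slope, $R^2$, $t = \mathrm{slope}/SE$, $n-2$ dof), computed
in closed form so the zero-perturbation limit returns slope and $R^2$ of
exactly 1 — the baseline and perturbed runs deliberately share the same
Monte-Carlo seed policy, so a zero-magnitude perturbation reproduces the
baseline counts bit for bit. A second regression restricted to the top half
of the baseline ranking tracks the entities an inspection programme would
actually act on.

**Redraw policy.** The package redraws one perturbed matrix per replicate
(default ten replicates per scenario). A variant that redraws the matrix for
every individual walk is provided (`redraw = "perRealization"`) but costs
$O(Y^2)$ per walk and is only sensible on small networks; for rank-stability
summaries the per-replicate design carries the same distributional content
at a fraction of the cost, and is the package's default.

## The synthetic generator

The vessel-movement records the analysis was designed for are proprietary,
so the package ships a generator that emulates their statistical structure
at the study's scale: 553 foreign ports in 126 countries, 30 domestic ports,
557 ships, 3000 voyages with a route-length distribution over 2–11 calls
(mean 8.50, hence ≈25,500 port-call events against the recorded 25,507), and
exponential leg durations with mean 7.9 days. Port popularity is a hub tier
over a Zipf-like tail (exponent 0.7 — small enough that all 553 ports are
observed, large enough that port sizes span two orders of magnitude);
the two hub ports carry a sampling weight calibrated so their realized
degree centrality is about four times the third-ranked port's, the dominant
two-hub pattern the study reports. Each foreign port carries a fixed
distance-to-destination score and voyages visit their ports in decreasing
distance order (with jitter), because ships sail toward the destination;
this geographic monotonicity is what gives arrival rates their
orders-of-magnitude spread across origins — with exchangeable call
positions, mid-ranked ports would be statistical ties and rankings among
them would be meaningless. The organism's range covers 36 countries of
which only 24 resolve on the network, emulating how a recorded range
intersects a trade network.

What the generator does **not** emulate: actual geography (distances are
abstract scores, there are no coordinates), seasonality, vessel-capacity
heterogeneity, container transshipment at hubs, and correlated liner-service
rotations. Tests passing on synthetic data therefore demonstrate the
*pipeline's* correctness and the model's qualitative behaviour, not the
published rankings themselves, which depend on the proprietary traffic data.

## Numerical choices

* Row closure tolerance $10^{-12}$ on `rates + absorption = 1`; validity
  methods enforce it on every constructed matrix.
* Per-origin RNG substreams derived deterministically from `(seed, origin
  id)` make estimates bit-reproducible and independent of origin order or
  subsetting; the compiled walker consumes R's own RNG stream.
* Walk length is capped at 10,000 steps; with row sums at most 0.9 the
  probability of hitting the cap is below $0.9^{10000}$. A truncated walk
  keeps its visits.
* `combineRates()` accumulates $\sum \log(1-\varphi)$ via `log1p` so many
  tiny rates do not lose precision.
* Ranking ties break lexicographically by entity id (deterministic output
  files); rank *statistics* use average ranks.
* Degree centrality counts each voyage's first call as a departure only and
  its last as an arrival only, so each leg contributes exactly one arrival
  and one departure.
* Consecutive duplicate calls within a voyage collapse with a warning (a
  zero-length leg carries no transmission).

## Problem sizes used by the tests

The test-suite experiments are sized for a desk run: oracle-equivalence
checks use $K = 10^5$ walks per origin on fixtures of at most 7 ports;
the rank-stability experiment runs the full 583-port synthetic network with
$K = 10^4$ walks per origin, ten replicates per scenario; enumeration
cross-checks use depth-20 path trees on 2–5-port fixtures with row sums low
enough for a $10^{-9}$ tail. The full study-scale simulation
($K = 2\times10^6$ over ~90 origins) runs in well under an hour on one core
thanks to the compiled walker.

## Known limitations

* First-order Markov: a container's onward path is independent of how it
  reached the current port. Reasonable at transshipment hubs, less so at
  small ports where cargo stays on one vessel.
* No vessel-capacity or cargo-type weighting: every vessel is assumed
  equally able to carry the organism.
* Arrival rates are relative (conditional on $\lambda_t$); they support
  ranking and comparison, not absolute probability statements.
* The complementary-product aggregation assumes independent pathways from
  distinct sources; correlated routes (shared liner services) would make it
  an upper-bound-leaning approximation.
* The arrival-conditioned extract truncates histories at ten prior calls;
  infestation earlier than that window is invisible to the model.
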