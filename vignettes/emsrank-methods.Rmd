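---
title: "Ranking emergency-service location configurations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking emergency-service location configurations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

emsrank ranks every possible placement of a fleet of emergency vehicles
over the zones ("atoms") of a service region. The pipeline has four
stages: (1) enumerate all allocations of the movable servers; (2) solve a
spatial queuing model for each allocation to obtain server workloads and
mean response times; (3) aggregate those measures into a composite index
with a constrained benefit-of-the-doubt DEA model plus an inverted
frontier; (4) analyze the resulting rankings for placement patterns. This
vignette documents the models, the design decisions behind them, and
their limitations.

## System model

A system holds: atom names; Poisson arrival rates per *sub atom* (each
atom is layered into a `serious` and a `regular` priority class);
a strictly positive matrix of mean journey times between atoms (not
required symmetric — intra-atom journeys may legitimately exceed
inter-atom ones, since they average over all point pairs); and one or
more fleets. Basic units (BSU) are movable and serve both priorities;
advanced units (ASU) are *dedicated*: they serve only serious calls and
stay pinned to base atoms.

Units matter: data files carry rates per hour (the convention of the
published demand tables) and times in minutes; the loader converts rates
to per-minute at the boundary so that rate × time products are
dimensionless loads everywhere inside the package. Atoms are numbered
from 1 in all files and reports.

A server's mean service time is modeled as an *on-scene component* plus
the mean journey to the calls it actually serves. Published per-type
response times are totals measured under the original deployment, where
every atom hosted a server and most dispatches were intra-atom; the
on-scene component is therefore recovered as the published total minus
the mean intra-atom journey time (the diagonal mean of the travel
matrix). Co-located servers of one type are treated as homogeneous, so
the published per-type average times are used rather than per-vehicle
values.

The two packaged case systems are transcriptions of a published Brazilian
SAMU data set (see `inst/extdata/README.md` for provenance notes,
including the synthetic choice of ASU base atoms, which the source does
not print).

## Enumeration

Allocations of `n` indistinguishable servers to `A` atoms are generated
partition by partition: each integer partition of `n` with at most `A`
parts is zero-filled and contributes `A!/prod(R_j!)` distinct
permutations, where `R_j` counts repeated terms (zeros included). The
total equals the weak-composition count `choose(n + A - 1, A - 1)`, which
the tests use as an independent oracle. Ordering is deterministic
(reverse-lexicographic), so configuration ids are stable across runs.
Types enumerate independently and combine as a Cartesian product;
dedicated fleets stay at their base atoms by default (`enumerate_dedicated
= TRUE` lifts that, reproducing the published grand totals 16,632 and
3,575 for the two cases).

One published table of configuration counts contains cells inconsistent
with its own counting formulas (e.g. 92,423 for 10 atoms and 10 servers
where weak compositions give 92,378); the formulas are treated as
normative and only formula-consistent cells are asserted in tests.

## The aggregated hypercube model

For one configuration, servers collapse into *groups* by (type, atom); a
state records the busy count of every group plus a queue descriptor
`(qs, qu)` — the numbers of serious and regular calls waiting. Three
state classes arise:

* **core** — any busy-count combination, empty queue: `prod(n_t + 1)`
  states;
* **dedicated-induced queue** — every basic group full while the
  dedicated groups are not all busy, with only regular calls waiting
  (free dedicated units cannot take them): with a single dedicated group
  of size `n_ds` and queue capacity `Q_l` this contributes
  `n_ds * Q_l` states. With several dedicated groups the count
  generalizes to `(prod(n_g + 1) - 1) * Q_l`; the packaged cases keep all
  dedicated units in one atom, where the two formulas coincide;
* **saturated queue** — everything busy with a two-priority queue
  multiset: `choose(Q_l + 2, 2) - 1` states.

Transitions implement the dispatch narrative of the source system.
Arrivals go to the first *free* group on the sub atom's preference list;
if none is free they join the queue (when allowed and capacity remains)
or are lost. Serious-call preferences are: dedicated groups nearest
first, then the basic group of the call's atom, then the remaining basic
groups in seeded random order (random backups). Regular-call
preferences: the local basic group, then the remaining basic groups by
journey time with seeded random tie-breaks. Service is non-preemptive: an
arrival never displaces a call in progress — structurally, arrival
transitions only ever increase busy counts or queue lengths.

Completions free a server in the group, which immediately takes the head
of the queue when one is waiting: serious before regular, FIFO within
class. A freed dedicated unit takes a waiting serious call but goes idle
if only regular calls wait. These rules keep the state space closed: a
serious call can be waiting only when every server is busy.

The exact per-call transition equations of the aggregation extension we
follow are published only in a supplement that is not part of our source
text; the structure above is our own reconstruction from the narrative
and is validated in two independent ways: (i) on systems small enough to
enumerate per-server states, the aggregated chain must equal the exact
`2^n` hypercube (it does, to 1e-8, including dedicated units); (ii) a
discrete-event simulator with the same policy must reproduce workloads
within replication confidence intervals (it does, over seeded batteries).
Single-group systems collapse to Erlang-B / M/M/n/K closed forms exactly.

### Steady state and measures

The generator is assembled as a dense base matrix up to 1,000 states
(these problems are a few hundred states, where sparse-class dispatch
overhead dominates) and as a sparse `Matrix` beyond; the balance
equations are solved directly, restricted to the states reachable from
the empty system, with one equation replaced by normalization. A
Gauss–Seidel sweep (tolerance 1e-10, at most 10,000 sweeps) stands
behind a size threshold of 20,000 states as the iterative fallback the
source names. Residuals above 1e-8 warn.

Workloads are expected busy fractions per group. Response times are
dispatch-probability-weighted means of (journey time from the serving
group's atom + the type's on-scene component). Two conventions need
stating:

* a call served *from the queue* cannot retain its origin in the
  aggregate state, so its serving group is attributed pro rata to the
  eligible groups' aggregate service rates; queue probabilities per sub
  atom are reported separately. Waiting time itself is *not* part of the
  response time used downstream, which is the travel-plus-on-scene
  quantity the published per-type times define (a `response = "travel"`
  flag restricts to the journey component);
* lost calls are excluded from means and reported as loss probabilities.

### Calibration

Service times and dispatch frequencies are mutually dependent: where a
group's calls come from determines its mean journey, hence its service
time, hence the steady state. `calibrate()` runs the natural fixed
point: solve, recompute each group's mean journey from its dispatch
frequencies, set service time = on-scene + journey, repeat until the
largest change falls below `tol` (default 1e-6 minutes, at most 50
iterations; non-convergence warns and flags rather than fails). With a
constant travel matrix the fixed point is immediate — the first update
changes nothing — which the tests exploit. On the packaged cases the
iteration converges in a handful of steps for every configuration.

## DEA/BoD composite index

Each configuration is a DMU with inputs `rho_i` (one workload per basic
server, servers expanded from groups in atom order) and outputs the
reciprocals of: the regular response time per atom (`y_h`), the serious
response time per atom (`y_h^S`), and the per-basic-server response time
(`z_i`) — so `O = 2A + n` outputs. Dedicated units appear on neither
side: their placement is fixed, their workload configuration-invariant.
Reciprocals are valid because no measure can be zero, and they penalize
long times more than a linear rescaling would.

The model is the output-oriented BCC (variable returns) multiplier form:
minimize the evaluated unit's virtual input minus a free scale factor
`w`, subject to its virtual output equal to 1, every DMU's virtual output
minus virtual input plus `w` nonpositive, and three families of weight
restrictions:

* a per-atom *assurance region*: the serious-call weight must exceed the
  regular-call weight, realized as `alpha_h^S - alpha_h >= eps`;
* *group contributions*: each of the three output groups must contribute
  at least `P%` of the evaluated unit's (unit-normalized) virtual output;
  `P = 0` disables these. The default `P = 20` keeps all three groups
  relevant while leaving 40% free, inside the feasibility bound
  `3 * 0.01 * P <= 1`. The source leaves its own `P` unstated;
* a non-Archimedean bound `eps` (default 1e-6 on the mean-normalized
  data scale — the source leaves the constant unvalued) on every weight.

The efficiency is `1/phi` with `phi >= 1` the optimum. Columns are
mean-normalized before solving purely for conditioning; efficiencies are
invariant to positive column scalings (a tested property). Note that the
assurance region and the group floors can jointly be *infeasible* for a
DMU whose serious reciprocal times are much larger than its regular
ones; real response-time data are far from that regime, but the solver
reports per-DMU status rather than aborting the batch, and relaxes `eps`
tenfold once before giving up.

Because a batch solves one LP per DMU against `N` frontier constraints,
the implementation solves the *envelopment* (dual) side — a few dozen
rows regardless of `N` — and recovers the multiplier weights as the dual
values of the envelopment rows; a direct multiplier-form solve is kept
for audits and as an automatic fallback on degenerate instances. The LP
engine is a dense two-phase simplex with Bland's-rule anti-cycling,
cross-checked in tests against an independent simplex implementation and
against textbook optima. No dedicated LP package is part of the
dependency footprint.

### Inverted frontier and composite

Ties on the standard frontier are broken by scoring each unit against the
frontier of *worst* practice: the same machinery with inputs and outputs
swapped. Two conventions were genuinely open and are resolved as
follows, both switchable in code: the assurance region follows the
serious/regular columns to the input side unchanged; the group floors,
which on the standard side are stated relative to the unit-normalized
output virtual, are taken relative to the virtual value of whichever side
carries the three response-time groups (this reduces exactly to the
printed constraints on the standard frontier and stays linear on the
inverted one).

The composite index is the normalized mean
`raw = (standard + (1 - inverted)) / 2`, scaled so the best unit scores
exactly 1 ("normalized" is not further specified in the source;
max-normalization is used and recorded). Ranks are by descending index
with stable id-order tie-breaks.

## Simulation oracle

`simulate_system()` is a discrete-event simulator sharing only the
*policy object* with the analytic code: Poisson arrivals thinned to sub
atoms, exponential service per group, the same preference lists,
non-preemptive two-class FIFO queue or loss. Events are processed in
time order with deterministic sequencing; statistics start after a warmup
(default 10% of the horizon) and come with batch-means confidence
intervals (20 batches). The validation battery prefers intervals built
from independent replications, whose t-coverage is exact. The simulator
is an oracle only; the ranking pipeline never uses it.

## Synthetic systems

`generate_synthetic_system()` draws systems with the structure of the
packaged cases: journey times uniform on 6–18 minutes with intra-atom
entries on the same scale, serious calls 5–15% of each atom's demand
(the cases sit near 10%), service means of realistic half-hour to
three-quarter-hour magnitude with dedicated units 10–40% slower, and a
total demand set so the fleet runs at about 50% utilization — busy enough
for interactions, comfortably inside stability (< 0.9). Draws are
reproducible per seed. What the generator does *not* emulate: travel
matrices with geographic structure (triangle-like inequalities,
clustering), demand imbalance beyond 5:1 across atoms, and empirical
service-time dispersion; conclusions from passing tests therefore concern
the correctness of the computations, not the realism of any particular
city.

## Numerical and reproducibility choices

* Queue capacity `Q_l` defaults to 5 per scenario; the source uses a
  priority queue of unstated capacity. `Q_l = 0` and the no-queue policy
  coincide.
* Random backup orderings derive from one seed per configuration
  (`derive_seed(master, id)`), recorded in every performance row;
  re-running a pipeline with the same inputs is byte-identical.
* Degenerate inputs fail loudly and early: non-square or non-positive
  travel matrices, negative rates, unknown priority tags, allocations
  that do not sum to fleet counts, state spaces beyond a 200,000-state
  cap, sub atoms with no eligible server group.
* Simplex tolerances: pivot 1e-9, phase-1 feasibility 1e-7, iteration
  cap 20,000 with Bland's rule after `5 (m + n)` pivots; ratio-test ties
  break deterministically toward low basis indices.
* Problem sizes exercised by the shipped tests: full 792- and
  715-configuration case batteries with both DEA frontiers; exact-model
  equivalence up to 4 servers; simulation batteries of 20 seeded toys
  with 5 replications each. These sizes were chosen to characterize the
  method at desk scale.

## Known limitations

* The aggregate queue forgets call origins; queued-call response
  attribution is pro rata (documented above). Per-origin queue-delay
  distributions are out of scope.
* Dedicated units never relocate during a scenario, and inter-fleet
  backup is one-directional (basic units back up serious calls, never
  the reverse for regular calls).
* Arrival rates are time-homogeneous; no time-of-day effects.
* The exact per-server model is exponential in fleet size and exists
  only as a small-`n` oracle.
* The published case rankings themselves are not reproduction targets:
  the source leaves calibration details, random dispatch matrices, `P`,
  `eps` and queue capacity unstated, so only structural counts, totals
  and qualitative placement patterns are comparable.
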