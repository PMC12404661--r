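---
title: "Modelling a two-member microbiota across a biphasic life cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a two-member microbiota across a biphasic life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasix)
```

## The system and the model

`biphasix` studies a two-species bacterial community that alternates between
a host-associated phase (the gut of the nematode *Caenorhabditis elegans*)
and a free-living environmental phase (growth on an agar plate). Species A is
the Pseudomonas-like environmental competitor, species B the
Ochrobactrum-like host specialist; the labels are configurable throughout.

The life-cycle model is deliberately minimal. Its assumptions:

* **Saturation.** Every phase, the population reaches the habitat's carrying
  capacity (`k_w` CFU per worm, `k_p` CFU per plate). This mirrors the
  empirical observation that worms are consistently colonized to similar
  loads in mono- and co-culture, and that lawns grow dense within the phase
  duration. Consequently only *composition* — the proportion `p` of species
  A — carries information between phases.
* **Static fitness.** Relative fitness in each habitat (`w_w_a` within the
  host, `w_p_a` on plate) is constant across cycles: the model describes
  ecological sorting in the absence of adaptation. Evolutionary change
  (new genotypes arising during passaging) is explicitly out of scope.
* **Discrete phases.** A cycle is worm colonization followed by plate
  growth; within-phase growth curves are not modelled. Parameters are
  endpoint summaries (persistence proportions, 3-day plate proportions),
  not rates.

One phase of selection with relative fitness `w` maps the proportion through
the replicator update

$$p' = \frac{p\,w}{p\,w + (1-p)(1-w)},$$

i.e. each phase multiplies the A:B odds by $w/(1-w)$. Boundaries are
absorbing (fixation and extinction are permanent), and `w = 0.5` is
neutrality (every `p` is a fixed point).

### Why the replicator normalization

The source formulation multiplies an abundance by a fitness and a carrying
capacity without renormalizing. Taken at face value with abundances near
`K`, the update overshoots the carrying capacity; read with proportions
instead of abundances, the occupied fraction *shrinks* every cycle whenever
both fitness values are below one — under which no species can ever rise to
dominance, contradicting the qualitative outcome the model is meant to
produce (the environmental competitor enriching over cycles in both
habitats). Some normalization must therefore have been implicit. We chose
the replicator map because it is the canonical two-type relative-fitness
update, it conserves the phase total exactly, and it reproduces the expected
dynamics: with plate fitness above one half, species A rises monotonically
toward fixation even when it is the worse within-host competitor. The
unnormalized proportional reading is retained as `mode = "literal"` in
`step_cycle()`/`simulate_lifecycle()` for transparency, and its monotone
decline is asserted in the test suite rather than hidden.

A related bookkeeping point: the printed companion equations subtract the
time-`t` abundance of species A from the phase total where only the
time-`t+1` value conserves that total. The implementation uses
`n_B(t+1) = K - n_A(t+1)`, treating the index as a typographical slip; this
is the only reading under which `n_A + n_B` equals the carrying capacity at
every step, a property the tests check exactly.

Cycle indexing is 1-based for reported milestones: "dominant after four
cycles" means the worm phase of cycle 4; cycle 0 is the actively inoculated
pre-cycle plate state.

An independent check used throughout the tests: iterating the odds
`odds <- odds * w/(1-w)` per phase must reproduce `simulate_lifecycle()`'s
proportions to 1e-12. The two formulations are algebraically equivalent but
numerically independent code paths.

### Stochastic serial-transfer mode

`simulate_stochastic()` emulates the passaging protocol of an evolution
experiment: each cycle a finite founder population (`n_worm_founders`,
default 1e3) colonizes the worms — a binomial draw around the
fitness-weighted plate proportion — and a `transfer_fraction` (default 0.1,
the protocol's 10% bottleneck) of the worm community is sampled binomially
to seed the next plate. Neither founder count is stated in the source
protocol; 1e3 is of the order of a worm's gut capacity divided by typical
uptake and is a package choice. In the infinite-size limit
(`transfer_fraction = 1`, founder counts of 1e7) the ensemble mean converges
to the deterministic trajectory; the test suite verifies a 3-standard-error
band at 500 runs per cycle (with a 1e-9 absolute slack purely to avoid 0/0
when late-cycle ensembles become numerically degenerate).

## Parameter estimation

* **Within-host fitness** is estimated from co-culture *short-term
  persistence* proportions: bacteria retained in the worm are the ones a
  host-associated passaging protocol transfers.
* **Plate fitness** is estimated from co-culture proportions on agar after
  3 days (the duration of the free-living phase in the mirrored protocol);
  the time point is configurable (`plate_time_h`).
* **Summary statistic.** The per-replicate proportions are summarized by
  their *median* by default. Under multiplicative lognormal CFU noise the
  replicate proportion has a logit-symmetric distribution whose median — not
  mean — equals the underlying fitness, so the median is both robust and
  consistent. The mean is available by argument.
* **Carrying capacities** are the maxima over replicates of species-summed
  totals: plate at the final growth time point, worm over established
  colonization and persistence. Mono- and co-culture records are never
  summed together; co-culture records are used by default (`co_only`).
* **Inoculum proportion.** Competition assays adjust the two species to
  equal optical densities, but the species differ in CFU per OD unit
  (1.86e9 versus 8.0e8 at OD 1). Whether the model's initial proportion
  should be 0.5 (OD basis) or ~0.70 (CFU basis) is ambiguous in the source;
  both are supported (`inoculum_proportion(basis = )`), OD basis is the
  default, and the choice must be declared in the pipeline configuration.
  The long-run dynamics are insensitive to it (the initial state only
  offsets the odds by a constant factor), but early-cycle proportions are
  not.
* **Zero-total replicates** (both species plated at zero) carry no
  compositional information and are dropped with a warning rather than
  imputed.

## The synthetic-data generator's stated world

`generator_config()` fixes the world once:

| parameter | default | why |
|---|---|---|
| `true_w_w_a` | 0.3 | host phase favours the host specialist B |
| `true_w_p_a` | 0.9 | plate phase strongly favours the fast grower A |
| `k_w` | 1e4 CFU/worm | order of magnitude of nematode gut loads |
| `k_p` | 1e9 CFU/plate | order of magnitude of a dense 6 cm lawn |
| `noise_sigma_log` | 0.3 | ~35% multiplicative CV, typical of CFU dilution plating; the source prints no replicate variance, so this is a package choice |
| `n_replicates` | 6 | the emulated assays use 4–6 |
| `timepoints_h` | 0, 24, 72, 168 | the plate growth sampling design |
| `mixing_weight` | 0.5 | worm colonization reflects both uptake from the plate and host filtering |

Noise is multiplicative lognormal on each CFU count: counts are strictly
positive and span orders of magnitude, making a log-scale error model the
natural default. Plate totals follow a three-step saturation profile (1e-3
of capacity at 0 h, 0.1 at 24 h, capacity from 72 h); plate composition
moves from the 1:1 inoculum at 0 h to the planted plate fitness from 72 h.
Persistence and release proportions equal the planted within-host fitness;
early and established colonization interpolate linearly between plate
composition and within-host fitness with `mixing_weight`. Mono-culture plate
means default to the full plate capacity (each species alone escapes
competition) while mono-culture worm means equal the co-culture per-species
means (within-host competition is absent in the emulated system).

What the generator does **not** emulate: dilution-series bookkeeping
(only final CFU per plate/worm are carried), count discreteness at low
abundance, within-gut spatial structure or immune dynamics, and any
between-replicate correlation. A green parameter-recovery test therefore
establishes that the estimators invert the generator's statistical
structure, not that they are robust to every feature of real assay data.

With `noise_sigma_log = 0` all generated proportions equal the planted
values exactly, which gives the end-to-end identity the pipeline tests use:
estimation on noiseless data reproduces the planted parameters, so the
simulated trajectory equals the one computed directly from the truth.

## The C-S-R classifier

Traits are scored against the community distribution: a trait contributes to
a strategy when it lies strictly above the community's 0.75 quantile
("high") or strictly below the 0.25 quantile ("low"). Competitor traits:
genome size, antibiotic pathways, siderophore pathways, catabolic pathways
(all high). Stress-tolerator: growth rate low, rRNA copies low, biofilm
genes high, auxotrophies high. Ruderal: catabolic pathways low, growth rate
high, rRNA copies high, codon usage bias high. The strategy with the highest
count wins; ties — including the all-zero case — are `intermediate`, and
ternary coordinates are the counts normalized to sum one (centroid when all
zero).

Decisions that were genuinely open:

* **Quantile definition.** Linear interpolation of order statistics
  (`stats::quantile` type 7, the default of the R ecosystem in which the
  original scoring was done); configurable. Because every observed trait
  value is itself an order statistic, strict threshold comparisons are
  invariant under any strictly monotone rescaling of a trait column — a
  property the suite tests with random monotone maps.
* **Strict inequalities.** "Belonging to the 0.75 quantile" is read as
  strictly above Q75. A community that is flat in a trait then scores
  nobody on it, rather than everybody.
* **Antibiotic pathways** are scored by the same quantile rule as all other
  counts for uniformity; a presence/absence mode
  (`binary_antibiotics = TRUE`) is available since "presence of antibiotics"
  admits a binary reading.
* **Fast/slow boundary.** Doubling exactly at the 5 h threshold is
  classified `slow` (the threshold separates the groups; a convention was
  required). The equivalent rate threshold is log(2)/5 ≈ 0.14 per hour.
* Only the maximal growth rate enters the growth criteria; codon usage bias
  contributes to the ruderal score directly but is not double-counted as a
  second slow-growth proxy for stress-toleration.

Trait inference itself (codon-usage growth models, pathway prediction,
virulence-gene screening) is out of scope: trait values enter via the TSV
trait table. The planted-strategy generator guarantees recovery when each
strategy is planted in under a quarter of the community — beyond that, the
planted extremes themselves drag the community quantile past some of them,
which is a property of quantile scoring, not a bug.

## Exact small-sample tests

The assays motivate exact rather than asymptotic inference: 4–6 replicates
per group.

* **Mann–Whitney U** enumerates all `choose(n1+n2, n1)` group labelings of
  the pooled mid-ranks, conditional on the observed tie pattern. The
  reported statistic is `min(U_x, U_y)` — the convention under which strong
  separations print as small values — and the two-sided p-value is the null
  probability of a minimum at least as small. For tie-free data this equals
  the classical doubled one-sided exact p.
* **Paired comparisons** use the exact Wilcoxon signed-rank test (zero
  differences dropped, mid-ranks on absolute differences, statistic `V` the
  smaller signed-rank sum, all `2^m` sign assignments enumerated). A
  "paired Mann–Whitney U" in the assay literature is read as this test; at
  six uniformly signed pairs it yields the statistic 0 with p = 2/64 ≈ 0.03,
  numerically consistent with that usage.
* Above a combined size of 20 both tests fall back to a tie-corrected
  normal approximation with continuity correction, announced by a message.
* **Multiplicity** is handled by Benjamini–Hochberg step-up FDR adjustment,
  returned in input order and capped at 1.

All exact p-values are checked against from-scratch brute-force oracles
(direct pairwise-comparison statistics over enumerated labelings / sign
vectors) and against the reference implementations in `stats` where those
are exact; the null distribution is memoized per (group size, mid-rank
multiset) so that the 10,000-replicate Type-I calibration runs in seconds
without changing any computed value. ANOVA, post-hoc families and GLM layers
used alongside these tests in the original analyses are deliberately not
re-implemented.

## Numerical conventions

* Proportions are clamped to [0, 1] after every update; fixation in
  monotonicity checks is declared at |p − {0,1}| < 1e-12.
* Boundary replicator inputs that would give 0/0 (e.g. p = 0 with w = 1)
  return p: extinction beats immigration-free fixation.
* Exact-test tail comparisons use a 1e-9 slack to absorb floating-point
  error in mid-rank sums.
* TSV round-trips preserve full double precision; validation errors name the
  offending row or column.
* The pipeline fans its top-level seed into per-stage sub-seeds by a fixed
  affine map modulo 2^31 − 1, so stages are independently reproducible and
  all derived seeds stay in integer range.

## Known limitations

* The model is strictly two-species and compositional; it cannot represent
  partial colonization, habitat vacancy, or more members.
* Fitness values are endpoint summaries; no growth-curve fitting is offered.
* The literal mode exists for comparison only and should not be used for
  inference.
* The stochastic mode's founder count is a free parameter the data do not
  constrain; conclusions about drift strength should be presented as
  conditional on it.
* Published per-species strategy calls for the motivating community depend
  on a supplementary trait table that is not redistributed here; the test
  suite reports this rather than asserting those calls.
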