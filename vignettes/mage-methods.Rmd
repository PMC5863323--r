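---
title: "Computing MAGE from CGM traces: model, solvers and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing MAGE from CGM traces: model, solvers and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magecalc)
```

## The statistic

The mean amplitude of glycemic excursions (MAGE) summarizes within-day
glycemic variability from a continuous glucose monitoring (CGM) trace —
typically 288 samples at 5-minute intervals over 24 hours. An *excursion* is
a swing between a local nadir and a local peak of the glucose curve; an
excursion is *countable* when its amplitude reaches the threshold, the
standard deviation of all glucose values in the 24-hour trace (SDBG). MAGE
is the arithmetic mean of the countable amplitudes taken in one direction
only — rises (nadir to peak) or falls (peak to nadir) — chosen by the
direction of the *first* countable excursion. `magecalc` also reports the
directional means separately (MAGE+ and MAGE−) and their average MAGEa,
which uses all countable excursions regardless of direction.

The classical "ruler and pencil" procedure leaves room for disagreement
about *which* extremes to count. This package formalizes the choice as an
optimization problem, so the counted set is defined — and reproducible —
rather than an artifact of scanning order.

## Extreme points and plateau merging

All local maxima and minima of the sampled curve are extracted first.
Runs of equal consecutive values (plateaus) are merged into the **last**
point of the run, which is then typed by the run's neighbours: a plateau
reached by a fall and left by a rise is a single nadir at the run's last
index, and symmetrically for peaks. By default the first and last trace
points are included as extreme points, typed by their single neighbour, so
an opening or closing excursion can be counted (`include_endpoints = FALSE`
switches this off). By construction the resulting kinds strictly alternate:
nadir, peak, nadir, …

No smoothing or denoising is applied before extreme detection; the
threshold, not a filter, decides which oscillations count.

## Selection as an integer program

Write $v_1, \dots, v_N$ for the extreme values in time order. A candidate
count is a subsequence $1 \le n_1 < \dots < n_K \le N$, $K \ge 2$, and it is
*feasible* when

* every adjacent *directional* amplitude passes the threshold: the step
  leaving a nadir must **rise** by at least
  $\tau = c \cdot \mathrm{SDBG}$ (default $c = 1$) and the step leaving a
  peak must **fall** by as much. Writing $s_k = +1$ when $n_k$ is a nadir
  and $-1$ when it is a peak, the constraint is
  $d_k = s_k\,(v_{n_{k+1}} - v_{n_k}) \ge \tau$; and
* consecutive selected indices differ by an odd amount, i.e. selected
  extremes alternate nadir/peak: $(-1)^{n_{k+1}-n_k} = -1$.

The direction requirement deserves emphasis, because the constraint is
often written with an absolute value, $|v_{n_{k+1}} - v_{n_k}| \ge \tau$.
The two are *not* equivalent: the absolute form admits monotone "staircase"
selections on drifting traces — a local peak *below* a later local nadir
counted as a falling excursion — which are physiologically meaningless
("the difference of a peak and an adjacent nadir" presumes the peak is the
higher of the two). They are also numerically poisonous: a staircase's
total amplitude telescopes to the difference of its endpoints regardless of
the interior points, creating whole families of *exactly* tied optima whose
rising/falling partitions differ, so the reported MAGE+ and MAGE− would
depend on the tie-break. With the signed form, ties are measure-zero on
continuous data and the optimum's direction labels always agree with the
actual signs of the selected steps. On any feasible selection
$d_k = |v_{n_{k+1}} - v_{n_k}|$, so the two forms coincide where they both
apply.

Among feasible selections the package maximizes first the number of
selected points $K$ and then the total amplitude $Z = \sum_k d_k$, breaking
remaining ties by the lexicographically smallest index vector (for
determinism). Maximizing $K$ first expresses "count every excursion that
qualifies"; $Z$ only disambiguates.

### Why the ordering matters

It is tempting to assume the fixed-$K$ optima are monotone,
$Z^*_{K-1} \le Z^*_K$, so that maximizing $Z$ alone would also maximize
$K$. That is false: a single point can never be inserted into an odd index
gap without breaking alternation (odd = odd + even), so the best pair —
e.g. a trace-spanning swing — need not extend to a triple, and the best
selection at a *smaller* $K$ can carry a *larger* total amplitude. The
instance with extreme values $(0.1,\, 10,\, 9.9,\, 1009.9)$ and threshold 0
has $Z^*_2 = 1009.8 > Z^*_3 = 1000.1$. The package therefore prioritizes
$K$ explicitly, and `max_total_amplitude()` computes the $Z$-only optimum
for comparison.

## Exact solvers (the oracles)

Two independent exact solvers anchor all validation:

* `solve_exact_bruteforce()` enumerates every subsequence (guarded to
  $N \le 20$; enumeration is exponential) — the ground truth on small
  instances.
* `solve_exact_dp()` is an $O(N^2)$ dynamic program over "best selection
  starting at extreme $i$", maximizing $(K, Z)$ lexicographically, with a
  reconstruction that returns the lexicographically smallest optimal index
  vector.

The suite checks them against each other on hundreds of random instances;
the dynamic program is the default solver in `calculate_mage()` because it
is exact and fast at any realistic $N$.

## The differential-evolution solver

`solve_de()` is the package's stochastic solver: an integer
differential-evolution search. The constraints are folded into a penalty objective
$$Y = -\textstyle\sum_k d_k + \mu \sum_k \max(0, g_k)^2 + \lambda \sum_k h_k^2,$$
with directional amplitude shortfall $g_k = \tau - d_k$ and parity
term $h_k = (-1)^{n_{k+1}-n_k} + 1$. A feasible selection has $Y = -Z$
exactly; any violation makes $Y > -Z$. The weights default to
$\mu = \lambda = 10^6 \max(\tau, 1)^2$, large enough that any violation
outweighs every attainable amplitude total, so the sign of the best $Y$
separates feasible from infeasible $K$ (a divergent weight schedule was
tried and performed no better than fixed large weights).

For each $K$ from 2 up to $N$, a population of `np` sorted integer vectors
over $\{1..N\}$ evolves for `generations` = 200 generations: difference
mutation $V = N_{r_1} + \mathrm{NINT}(F (N_{r_2} - N_{r_3}))$ with entries
clamped into $[1, N]$, binomial crossover with one guaranteed mutant
coordinate, re-sorting, and greedy selection on $Y$. A $K$ counts as
feasible when its best $Y < 0$ *and* the best vector passes the explicit
feasibility check (with finite weights a vanishing amplitude shortfall can
leave $Y < 0$); the best vector at the largest feasible $K$ is returned.
Halves in NINT round away from zero. Vectors with repeated indices are
legal intermediates — a repeat creates an even (zero) gap and is penalized
away — and there is no repair step.

### Tuning and the two stabilizers

The population defaults were calibrated against the exact dynamic program
on random selection problems (see below), not taken from generic DE
folklore, because the encoding is unusual: the vectors are *sorted*, so
coordinates are strongly coupled, and the space is integer, so small
mutation steps round to zero. Two consequences:

* A conventional high crossover rate is destructive here; `cr = 0.1` with
  `f = 1` (difference vectors applied unrounded) searches far more
  reliably than the common (0.9, 0.5) pairing, which reached only ~65%
  agreement with the exact optimum on random instances.
* Integer rounding makes the population collapse: with default-style
  settings the end-of-run population held ~2% distinct vectors. After each
  generation, members that duplicate an earlier member are redrawn
  uniformly (`reinit_duplicates`, default on); the first copy — hence the
  incumbent best — is always kept, so the greedy guarantee (best $Y$ never
  worsens) is preserved.

Additionally, because selections at consecutive $K$ typically share most of
their points, each $K$'s initial population is seeded with `warm` = 20
single-index extensions of the best feasible vector found at $K - 1$; the
other `np` − 20 members are drawn uniformly as usual, so the search space
stays covered. With `np = 200`, `f = 1`, `cr = 0.1`, G = 200 and both
stabilizers on, the solver reproduces the exact $(K^*, Z^*)$ on at least
95% of 200 random instances with $N \le 30$ (the shipped validation bar;
`mage_selftest()` recomputes the rate, and a 200-instance sample of a
~95-97% process fluctuates a couple of points around its mean). Disagreements are near-misses at
large $N$ — one or two points short of $K^*$, or the right $K^*$ with
slightly smaller $Z$ — and the returned selection is always feasible. All
settings are exposed in
`de_config()`. The exact DP remains the default solver; `solver = "de"`
exists for studying the evolutionary search itself.

## MAGE from the optimal selection

Given the optimal selection, rising amplitudes are averaged into MAGE+,
falling ones into MAGE−. MAGE equals MAGE+ when the first selected extreme
is a nadir, MAGE− otherwise; MAGEa is the mean of the two directional
means. When only one direction occurs (e.g. a single countable excursion),
the missing mean is reported as `NA` — never 0, which would bias batch
averages — and MAGEa falls back to the defined one. When no countable
excursion exists the result has `n_excursions = 0`, direction `"none"`, and
MAGE is `NA` by default (`empty_policy = "zero"` reports 0 instead).

Because every counted amplitude passes the threshold, MAGE ≥ SDBG whenever
any excursion is counted — a useful smoke test on real data.

## Input handling

CSV import (`read_cgm_csv()`) accepts a timestamp column (ISO 8601,
`strptime` formats, or numeric seconds/minutes) and a glucose column in
mmol/L or mg/dL; mg/dL is converted with the fixed divisor 18.016 (glucose
molar mass 180.16 g/mol). Rows are sorted by time; duplicate timestamps are
an error rather than being averaged, since silent averaging would change
SDBG and hence the threshold. `segment_24h()` cuts consecutive 24-hour
windows from the trace start; a window counts as complete when its samples
span at least 20 hours with no gap above 2 hours. These two tolerances are
a policy choice — a nominal 24-hour recording with minor sensor dropouts
should still qualify — and both are arguments. Gaps are not interpolated.

### Defaults with units

| parameter | default | meaning |
|---|---|---|
| `sd_ddof` | 1 | SDBG denominator $n-1$ (sample SD); 0 gives $n$ |
| `threshold_multiplier` | 1 | threshold $= c \cdot$ SDBG, mmol/L |
| `comparator` | `ge` | amplitude qualifies when $\ge$ threshold |
| `include_endpoints` | `TRUE` | trace endpoints count as extremes |
| `np`, `f`, `cr`, `generations` | 200, 1, 0.1, 200 | DE population, scale, crossover, generations |
| `min_span_hours`, `max_gap_hours` | 20, 2 | 24-h window completeness |

The SDBG denominator and the comparator deserve a note: sample SD ($n-1$)
is the common convention in the clinical literature, and the formal
constraint "$\ge$ SDBG" is used for qualification even though prose
descriptions often say "exceeding"; both are switchable because published
implementations differ on both points.

## The synthetic generators

`generate_alternating_trace()` builds piecewise-linear traces that rise and
fall by specified amplitudes from a baseline, sampled at 5-minute spacing,
and returns the implied ground truth (vertex positions, MAGE+, MAGE−, MAGE,
MAGEa, and the realized ratio of smallest amplitude to the trace's own
SDBG). `generate_noisy_trace()` adds Gaussian noise and Fig-2-style
plateaus; `generate_random_problem()` draws random alternating
extreme-value sequences with the threshold set at a chosen quantile of the
adjacent amplitudes, so qualifying and non-qualifying amplitudes both
occur.

One subtlety: the ratio min(amplitude)/SDBG is *scale-invariant* — scaling
all amplitudes scales the trace SD identically — so a generator cannot fix
it by rescaling. It is a shape property. Drawing amplitudes within a factor
of two of each other (2.5–5 mmol/L in the validation suites) keeps the
ratio above 1.5, so every planted excursion clears the threshold and the
pipeline must recover the planted statistics exactly; the generator records
the realized ratio (`sd_multiple`) and the suites assert it.

What the generators deliberately do **not** emulate: physiological
glucose–insulin dynamics, sensor drift or autocorrelated noise, meal-time
structure. Passing the planted suites shows the *selection machinery* is
exact under known ground truth; it does not certify agreement with manual
counting on clinical traces, which requires clinical data.

## Validation suites and problem sizes

The shipped suites (also reachable via `oracle_agreement()`,
`mage_selftest()` and the CLI `selftest` subcommand) use these sizes,
chosen to exercise each component well past its defaults while staying
desk-scale:

* DP vs enumeration: 500 random problems, $N \in [4, 12]$ — identical
  $(K^*, Z^*)$ required on all.
* DE vs DP: 200 random problems, $N \in [4, 30]$, default configuration —
  at least 95% identical $(K^*, Z^*)$; the DE total amplitude never exceeds
  the exact maximum feasible total.
* Planted recovery: 50 noiseless traces with 2–10 excursions — exact
  recovery (tolerance $10^{-9}$).
* Invariances (1000 property cases): translation invariance, scale
  equivariance, time-reversal swap of MAGE+/MAGE− (on plateau-free traces;
  plateau merging keeps the *last* run index, which reversal maps to the
  first, so plateau traces are excluded by design), MAGE ≥ SDBG, and strict
  alternation of extracted extremes.
* Penalty consistency: $Y = -Z$ iff feasible, on random selections.

## Known limitations

* The DE solver is stochastic: on hard instances ($N$ near 30 with many
  near-threshold amplitudes) it can return one point fewer than $K^*$ or a
  slightly smaller $Z$. Use the default DP solver for exact results.
* Time-reversal symmetry of the *reported* numbers can break on traces
  with plateaus (the merge rule is intentionally asymmetric) and on
  instances with exactly tied optima (ties are resolved
  lexicographically).
* No gap interpolation: a window failing the completeness policy is
  dropped, not imputed.
* `comparator = "gt"` makes the penalty identity $Y = -Z \iff$ feasible
  fail exactly at amplitude = threshold (a measure-zero case); the penalty
  form follows the "$\ge$" constraint.
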