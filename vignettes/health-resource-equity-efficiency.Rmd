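---
title: "Measuring equity and efficiency of regional health-resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity and efficiency of regional health-resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equidea)
```

## The problem

Health administrations allocate inputs — medical institutions, beds,
health staff — across regions, and those regions turn them into services:
outpatient visits and discharged patients. Two questions follow. Is the
allocation *equitable*, relative to where people live and how much
territory must be covered? And is it *efficient*: does each region get as
much service output from its inputs as the best-performing regions do,
and is that productivity improving over time?

equidea answers both from a single long-format panel: one row per
decision-making unit (DMU; typically a province) and year, with input
quantities, output quantities, population, land area and a region-group
label. The package was designed around panels shaped like the 31
province-level divisions of mainland China observed over five years,
grouped into eastern (11), middle (8) and western (12) regions, but
nothing restricts it to that geography.

## Equity measures

For a year, a resource and an allocation base (population or area),
`make_shares()` forms each unit's resource share $X_i$ and base share
$Y_i$, both summing to one.

**Lorenz curve and Gini.** Units are sorted by ascending resource-per-base
ratio $X_i/Y_i$ (ties broken by unit identifier, so results are
deterministic); the Lorenz curve plots cumulative $X$ against cumulative
$Y$. The headline Gini coefficient is twice the area between the curve
and the diagonal, accumulated by trapezoids over the sorted units:

$$G \;=\; 1 - \sum_i Y_{(i)}\,\bigl(\mathrm{cum}X_{(i-1)} + \mathrm{cum}X_{(i)}\bigr).$$

The package also computes the **Hoover (Robin Hood) index**
$H = \tfrac12\sum_i |X_i - Y_i|$, the share of the resource that would
have to move to reach perfect proportionality. $H$ equals the maximum
vertical gap between the Lorenz curve and the diagonal, and
$H \le G$ always. Both are exposed because applied equity studies
sometimes print the Hoover form under the Gini's name; where the two
differ materially, reporting both is more honest than guessing. The
headline value used by `gini_table()`'s `band` column is the trapezoid
Gini, classified with the conventional half-open bands (< 0.2 absolute
equality, 0.2–0.3 relative equality, 0.3–0.4 proper equality, 0.4–0.5
relative inequality, ≥ 0.5 serious inequality; `gini_band()` documents
the edge behaviour exactly).

**Theil index.** `theil()` computes the population-weighted mean log
deviation

$$T \;=\; \sum_i P_i \,\ln\!\frac{P_i}{R_i},$$

with $P_i$ the base share and $R_i$ the resource share. Natural
logarithms are used throughout — the index is only additively
decomposable on one log base, and mixing bases silently breaks the
decomposition. A unit with zero resource share makes the index undefined
and raises an error rather than being epsilon-patched; the Gini, by
contrast, tolerates zeros. `theil_decompose()` splits $T$ for grouped
units into

$$T_\text{intra} = \sum_g p_g t_g, \qquad
  T_\text{inter} = \sum_g p_g \ln\!\frac{p_g}{y_g},$$

where $t_g$ is the Theil index of group $g$ on shares renormalised
within the group. The two components sum to the pooled index exactly (to
floating-point round-off; the test suite asserts $10^{-10}$), so
`contribution_rates()` can attribute total inequality to
within-region versus between-region disparity. For multi-year series the
default contribution rate is the arithmetic mean of the yearly ratios
$T_\text{intra}/T$; a pooled mode (`sum(T_intra)/sum(T)`) is available,
and the choice matters at the second decimal on real panels.

## Efficiency: output-oriented DEA

`dea_radial()` solves, for DMU $o$ with inputs $x_o$ and outputs $y_o$,

$$\max \varphi \quad \text{s.t.}\quad
  X\lambda \le x_o,\;\; Y\lambda \ge \varphi\, y_o,\;\; \lambda \ge 0,$$

adding $\sum_j \lambda_j = 1$ under variable returns to scale (the BCC
model). $\varphi \ge 1$ is the feasible equiproportional expansion of all
outputs; technical efficiency is reported as $1/\varphi \le 1$, the
convention of DEAP-style software. Slacks come from a second stage that
maximises the total input excess plus output shortfall at fixed
$\varphi$ (`dea_slacks()`); the two-stage formulation avoids the
numerical fragility of non-Archimedean $\varepsilon$ weights. In
emitted tables, input slacks carry a negative sign (reduction needed)
and output slacks a positive one, mirroring the slack tables of the
applied literature.

Returns-to-scale classification (`dea_rts()`) uses the Banker criterion
on the CRS solution: $\sum_j \lambda_j$ equal to / below / above one
means constant / increasing / decreasing returns. Because the optimal
$\lambda$ need not be unique, the package solves two auxiliary LPs for
the minimum and maximum of $\sum\lambda$ over the optimal set and
reports CRS whenever 1 lies in that interval (tolerance $10^{-6}$).

**The LP engine.** The envelopment problems are dense, tiny (at most a
few dozen variables and a dozen rows) and — on constructed validation
panels — heavily degenerate, with exactly proportional constraint rows.
The package therefore ships its own two-phase primal simplex using
Bland's anti-cycling rule (`R/lp.R`): Bland's rule is slower than
steepest-edge pivoting but provably terminates under degeneracy, which is
the failure mode that matters here. Redundant constraints are detected
after phase one and dropped. Each input/output row is rescaled to order
one before solving (the radial score is units-invariant; slacks are
scaled back), and nonpositive data are rejected outright rather than
epsilon-replaced. The test suite checks the solver against exhaustive
vertex enumeration on small technologies and against an independent
simplex implementation on non-degenerate toys.

## Productivity: the Malmquist index

For adjacent years $t, t{+}1$, writing $D^a(b)$ for the CRS output
distance function of the period-$a$ frontier at the period-$b$
observation, `malmquist_pair()` reports per DMU:

* $\text{effch} = D^{t+1}(t{+}1)/D^{t}(t)$,
* $\text{techch} = \bigl[\tfrac{D^t(t+1)}{D^{t+1}(t+1)}\cdot
  \tfrac{D^t(t)}{D^{t+1}(t)}\bigr]^{1/2}$,
* $\text{pech}$ as effch computed under VRS,
* $\text{sech} = \text{effch}/\text{pech}$,
* $\text{tfpch} = \text{effch}\times\text{techch}$.

This is the standard Färe–Grosskopf–Norris–Zhang construction: CRS
distances for the productivity index and its technology/efficiency
split, VRS only for the pure-efficiency component. It keeps both
identities ($\text{tfpch} = \text{effch}\cdot\text{techch}$,
$\text{effch} = \text{pech}\cdot\text{sech}$) exact by construction and
avoids the cross-period infeasibility that pure-VRS formulations suffer;
under constant returns with strictly positive data the cross-period LPs
are always feasible. `malmquist_summary()` aggregates by geometric means
— per DMU across period pairs and per pair across DMUs — and tabulates
frequency counts of components above / equal to / below one, with
membership in the "equal" class decided after rounding to three
decimals, the way such published tables are read. Unrounded means are
kept alongside: a table can legitimately print a mean of exactly 1.000
while most units differ from 1 in the third decimal.

Time-reversal symmetry (swapping the two years inverts every component)
and chain consistency on noise-free panels are asserted in the tests to
$10^{-9}$.

## What the synthetic generator emulates

`gen_panel()` draws grouped panels that reproduce the statistical regime
the analyses assume, with defaults frozen at:

* 31 DMUs in groups of 11/8/12, five yearly waves (2013–2017);
* populations log-normal (log-sd 0.6, western group smaller), areas
  log-normal with a wide spread (log-sd 1.1, western areas largest) and
  constant over time;
* resource and output quantities *population-linked*: each DMU's value is
  population × a log-normal per-capita level. Within-group per-capita
  log-sd is 0.5 for institutions and 0.25–0.3 for the other quantities,
  which places population-based Ginis near 0.26 and 0.10–0.15
  respectively — the "institutions less equitable than beds and staff"
  pattern typical of province panels — while the population-independent
  area spread pushes area-based Ginis above 0.5;
* a mild east > middle > west per-capita gradient (log offsets
  +0.08/0/−0.12 for inputs), so the within-group Theil component
  dominates the between-group one, as observed in national panels;
* deterministic annual growth factors per quantity (6.6–9.7%), so every
  series rises steadily; with input growth slightly outpacing output
  growth, the implied Malmquist tfpch sits just below 1.

Each quantity draws from its own named pseudo-random stream derived from
the single integer seed, so adding a quantity to a spec never perturbs
the draws of existing ones, and identical seeds give bit-identical
panels.

What it does **not** emulate: spatial correlation between area and
population (real large-area provinces are not population-independent,
so synthetic area-based Ginis run higher than real ones), measurement
error, administrative re-definitions, or any attempt to match real
yearbook marginals province by province. Passing tests on these panels
therefore demonstrate correctness of the *measures*, not calibration to
any particular country's data.

`gen_frontier_panel()` serves the DEA and Malmquist stages. All DMUs
share one input mix and differ in scale; efficient outputs are
proportional to scale in a fixed output mix, so the production frontier
is a single constant-returns ray, and a DMU whose outputs are contracted
by $c_j \in (0,1]$ has true radial score exactly $1/c_j$ — by algebra,
not by any solver. An earlier design drew heterogeneous input mixes, but
then the cone spanned by the frontier DMUs need not contain the other
DMUs' input vectors and the nominal "truth" $1/c_j$ is simply wrong;
collapsing to a common ray is what makes the ground truth exact. The
year-over-year Hicks-neutral shift multiplies efficient outputs by $g$,
so true techch is $g$ for every DMU and true effch is 1. An optional
multiplicative output noise knob exists for property tests that need
genuinely different years (for example time-reversal), and defaults to
zero so that truth-recovery tests are exact.

## Numerical choices and degenerate inputs

* LP pivot tolerance $10^{-10}$; RTS interval tolerance $10^{-6}$;
  radial truth recovered to $10^{-6}$ or better on noise-free frontiers
  (observed: $\sim 10^{-15}$).
* All inter-module exchange is full precision; rounding (4 decimals for
  equity tables, 3 for DEA/Malmquist) happens only in `run_report()`'s
  emitted CSVs.
* Lorenz/Gini sorting breaks ties by unit identifier; permuting input
  rows changes nothing.
* Zero resource totals, zero bases, duplicate (dmu, year) rows,
  unbalanced Malmquist pairs and ungrouped DMUs are hard errors with the
  offending units named. Missing (dmu, year) combinations are allowed
  for per-year equity analyses but rejected by `malmquist_pair()`.
* `share_vector()` tolerates $X_i = 0$ (Gini) but `theil()` refuses it.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
study's native scale — 31 DMUs × 5 years, 3 inputs, 2 outputs — which
solves in seconds; property suites use 1,000 random share vectors and a
few dozen randomised panels. Published national summary tables
(densities, Gini, Theil, Malmquist components; see `reference_table()`)
are bundled as plain-text CSV so the arithmetic-consistency checks and
examples need no external data.

## Known limitations

* Scores are not bias-corrected and carry no confidence intervals
  (no DEA bootstrap); input orientation and super-efficiency are out of
  scope, as are global-frontier or fixed-base Malmquist variants.
* The per-area density is labelled per 1,000 km²; published yearbook
  tables print per-area densities on a different (ambiguous) area unit,
  so per-area *levels* are not comparable across sources, only trends.
* Province-level raw yearbook inputs are not redistributable here, so
  full reproduction of published province tables is impossible; the
  bundled summary tables support arithmetic consistency checks only.
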