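---
title: "A gene-flow model of selection response in two-tier honeybee populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gene-flow model of selection response in two-tier honeybee populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflow)
```

## The model

Managed honeybee populations are typically split into a small *breeding*
tier, whose performance-tested colonies undergo truncation selection, and a
much larger unselected *passive* tier that benefits only indirectly. Genetic
material flows between the tiers along two routes:

* **drones**: a queen mating freely in the air mates with drones whose dam is
  a breeding colony with probability $p$ (in a well-mixed area,
  $p \approx N_b/(N_b+N_p)$);
* **queens**: a fraction $q$ of passive queens is reared from (unselected)
  breeding colonies.

The quantity tracked is the mean true breeding value of *colonies*, i.e. of
worker groups; a colony value is half the queen's breeding value and half the
mean value of the drones she mated with, and it equals the expected breeding
value of a queen reared from that colony. Writing $B_t$ and $P_t$ for the
mean colony values of the two tiers in year $t$ (a colony is labelled by the
birth/mating year of its queen), the transmission bookkeeping with a 2-year
queen–dam interval and 2-year-old drone dams gives, for free mating and
constant parameters,

$$B_t = \tfrac12 B_{t-2} + \tfrac{p+q-pq}{2} B_{t-4}
      + \tfrac{(1-p)(1-q)}{2} P_{t-4} + \tfrac{1+p}{2} S_1,$$
$$P_t = \tfrac{q}{2} B_{t-2} + \tfrac{p+q-pq}{2} B_{t-4}
      + \tfrac{1-q}{2} P_{t-2} + \tfrac{(1-p)(1-q)}{2} P_{t-4}
      + \tfrac{p}{2} S_1,$$

where $S_1$ is the genetic selection differential of the colonies chosen to
produce breeding queens. Under controlled mating on isolated stations the
paternal path runs through sister drone-producing queens (DPQs) whose common
dam is a selected colony three years older than the mated queen, and the
breeding tier decouples from the passive one:

$$B_t = \tfrac12 B_{t-2} + \tfrac12 B_{t-3} + \tfrac{S_1+S_2}{2}.$$

`iterate_gene_flow()` iterates these recursions exactly (also in a
term-by-term time-varying mode with per-year $p_t$, $q_t$, $S_{1,t}$,
$S_{2,t}$; the two modes are cross-checked in the tests).

Subtracting the recursions yields a closed recursion for the genetic lag
$D_t = B_t - P_t$, and linear-recurrence fixed-point arguments give the
asymptotic values returned by `predict_uncontrolled()` and
`predict_controlled()`:

| quantity | uncontrolled | controlled |
|---|---|---|
| annual gain $\Delta B = \Delta P$ | $\frac{p+q}{3+3q} S_1$ | $\frac{S_1+S_2}{5}$ |
| genetic lag $D$ | $\frac{S_1}{1+q}$ | $\frac{6}{p+2q-pq}\frac{S_1+S_2}{5} - \frac{p}{p+2q-pq} S_1$ |
| time lag $T$ (years) | $\frac{3}{p+q}$ | $D/\Delta B$ |

The controlled-mating gain is the classical ratio of summed selection
differentials to summed generation intervals ($2+3$ years). Degenerate
denominators ($p+q=0$, resp. $p+2q-pq=0$) are returned as `Inf` with a
`divergent` flag rather than raising, so grid sweeps over the unit square
complete.

```{r}
predict_uncontrolled(p = 1, q = 1, s1 = 1)
predict_controlled(p = 0.5, q = 0.5, s1 = 1, s2 = 1)
```

## Numerical choices

**Initialization and the parity sub-chains.** The recursions start from an
unselected base: all pre-start means are zero and the selection differentials
act from year 1 (`initial_state()`). One consequence deserves emphasis: the
uncontrolled recursions contain only even lags, so the even-year and odd-year
sub-chains never exchange information. From a parity-symmetric start the two
chains are *identical* ($B_{2k} = B_{2k-1}$ exactly), which makes the annual
first difference $\Delta B_t$ oscillate permanently between $0$ and twice the
asymptotic gain — the characteristic root $x=-1$ of the gain recursion never
decays. The genetic lag and all controlled-mating quantities are unaffected.
The package therefore reports trajectories with their exact annual
differences but extracts asymptotes and detects convergence with the
parity-robust two-year mean gain $(B_t - B_{t-2})/2$
(`trajectory_asymptotes()`); convergence is flagged at the first year where
this gain changes by less than `tol` against the previous year and the lag by
less than `tol` against two years back (default `1e-9`; the model itself
states no criterion). Real populations do not show the oscillation because
dam and drone-dam ages vary — as they do in the stochastic simulator.

**Convergence analysis.** `recursion_spec()` and `characteristic_roots()`
expose the lag polynomials of the four scalar recursions (lag and gain, per
mating system) and their roots, computed as companion-matrix eigenvalues.
Recursions on a two-year step are analyzed per parity chain and the dominant
modulus is converted to a per-year factor by square root so all recursions
are comparable. For the gain recursions the roots $x = \pm 1$ are structural
(linear growth, parity interleaving) and excluded from the transient modulus;
for the lag recursions nothing is excluded — at $p+2q-pq = 0$ the unit root
is real non-convergence. The homogeneous parts of both gain recursions are
parameter-free (per-year contraction $\sqrt{1/2}$); only the *lag* slows
down as $p$ and $q$ shrink, with per-2-year dominant root
$\bigl(a+\sqrt{a^2+4b}\bigr)/2$, $a = \frac{1-q}{2}$,
$b = \frac{(1-p)(1-q)}{2}$. This is the quantitative content of the
observation that for a self-sufficient passive tier ($q$ small) a 20-year
horizon is simply too short for the lag to reach its asymptote: at
$p = 0.5, q = 0$ the per-year factor is $\approx 0.95$ and the year-20 lag is
still several percent away (`years_to_converge()`), while the closed form is
exact in the limit. Fixed-tolerance grid comparisons in the tests use this
same root analysis *a priori* to determine where a 400-year horizon provably
cannot reach `1e-6` (one near-degenerate corner of the controlled grid) and
assert convergence at the analytically required horizon there instead.

## The individual-based simulator

`simulate_breeding()` is a stochastic check of the deterministic theory under
an infinitesimal model, emulating the population structure of the simulation
study that the recursions idealize:

* **Individuals.** Diploid queens and haploid drones carry breeding values; a
  colony value is $\tfrac12$ queen $+\ \tfrac12$ mean of the
  `drones_per_mating` mates (default 12 of "up to 20"; the identity holds
  exactly in the output by construction). A daughter queen's value is her
  dam *colony's* value plus a Mendelian deviation; a drone's value (on the
  diploid scale) is his dam *queen's* value plus a Mendelian deviation. Both
  deviations are normal with SD $\sigma_A/\sqrt2$ — the simplest convention
  whose expectations reproduce the transmission bookkeeping above, which is
  all the validated quantities depend on. Variances are not calibrated
  (no explicit Bulmer correction; the realized colony-value spread shrinks
  naturally under selection and enters only through realized differentials).
* **Selection.** Breeding-value estimation (a honeybee BLUP in practice) is
  replaced by an index frozen at colony creation:
  $\rho \cdot \text{value} + \sqrt{1-\rho^2}\,\mathrm{sd}(\text{value})\,z$,
  so the index–value correlation is the accuracy $\rho$ (default 0.8, a
  typical colony-level accuracy; $\rho = 0$ means random selection). Dams of
  breeding queens are the top `sel_frac_dam` (default 20%) of the cohort two
  years back, each contributing an equal share of daughters; DPQ dams are the
  top `n_stations` colonies of the cohort three years back. The selected
  proportions of the original study are unpublished; they need not be matched
  because validation is self-calibrating — realized differentials
  $\bar S_{j,t} = \bar B_{j,t} - \bar B_t$ are *measured* at selection time
  and plugged into the predictors.
* **Age structure.** Breeding dams: fixed 2 years. Passive dams and
  free-mating drone dams: uniform on 1–3 years (mean 2). DPQ granddam path:
  3 years, with station drones the same age as the queens they mate. These
  mirror the validation study's layout; the recursions assume the means.
* **Tiers and flow.** Passive queens take a uniformly chosen *unselected*
  breeding colony as dam with probability $q$; free-mating drone dams are
  breeding queens with probability `p_drone` (default $N_b/(N_b+N_p)$,
  overridable); the passive reproduction routine never sees the mating
  system.
* **Genetics modes.** `aggregate` (one value, SD `sigma_a`) or
  `maternal_direct` (direct and maternal components with heritabilities and
  correlation `r_md`, scaled so the total variance is `sigma_a^2`; selection
  acts on the total, components are reported separately).
* **Reproducibility.** One master seed; per-replicate streams derived from it
  deterministically, so replicates are independent and byte-reproducible.

What a green validation run establishes is therefore that the *expected*
transmission dynamics of the simulator match the recursions — not that the
simulator reproduces any particular real program's differentials (BLUP
accuracy structure, negative component differentials under strongly negative
$r_{md}$, inbreeding, drift and long-term nonlinearity are all outside the
model).

## Validation pipeline

`run_validation_study()` runs a scaled-down scenario grid (defaults:
$N_b = N_p \in \{250, 500\}$, $q \in \{0.5, 0.75, 1\}$, both mating systems,
10 replicates, 20 years), averages realized gains, lags and differentials
over years 8–17 (differentials stabilize from year 8), predicts each
scenario from the closed forms with the *realized* $\bar S_1, \bar S_2$, and
regresses simulated on predicted values. The headline statistics are the
least-squares slope through the origin and the squared Pearson correlation
(the comparison is against an equality line and no intercept is part of the
claim; the with-intercept fit is reported alongside). Scenarios with
$q < 0.5$ are deliberately outside the default grid: there the lag recursion
contracts too slowly for a 20-year window, which is a property of the window,
not of the formulas — `years_to_converge()` quantifies it and the tests
verify that the gap closes monotonically as the horizon grows.

`reconstruct_passive_mean()` implements the reconstruction of passive colony
means from queen means (half from the year's passive queens, half from drone
dams 1–3 years back, mixed by $p$) used when worker groups of the passive
tier are not tracked; since this simulator does track them, the
reconstruction is validated against the directly simulated means.

```{r, eval = FALSE}
study <- run_validation_study(seed = 1234)
study$report$r_squared   # pooled squared correlation, ~0.999 at these scales
study$report$slope       # slope through the origin, ~0.99
```

## Tunable parameters at a glance

| parameter | meaning | default | why |
|---|---|---|---|
| `p` / `p_drone` | breeding-dam probability of a free-mating drone | $N_b/(N_b+N_p)$ | well-mixed mating area |
| `q` | passive queens with breeding dams | scenario | breeding-plan choice |
| `s1`, `s2` | selection differentials (BV units) | measured in sims; $S = i\rho\sigma$ *a priori* | `selection_differential()` |
| `sigma_a` | additive-genetic SD | 1 | results scale linearly |
| `rho` | index accuracy | 0.8 | typical colony-level accuracy |
| `sel_frac_dam` | dam-selected fraction | 0.2 | strong but realistic truncation |
| `drones_per_mating` | mates per queen | 12 | "up to 20" observed |
| `dpqs_per_station` | sister DPQs | 8 | standard station layout |
| `tol` (iterate) | convergence tolerance | $10^{-9}$ | no criterion stated by the model |

## Limitations

Means only: no inbreeding, no genetic drift of variances, no Bulmer
correction, no genomes or pedigree BLUP, no spatially inhomogeneous mating,
and linear gain forever — over many generations real programs bend away from
these predictions. The closed forms assume constant parameters and rigid
generation intervals; the time-varying recursion mode relaxes the former,
the simulator the latter.
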