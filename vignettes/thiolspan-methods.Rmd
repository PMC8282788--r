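---
title: "Methods: overlap statistics, lifespan curves and assay summaries in thiolspan"
author: "thiolspan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap statistics, lifespan curves and assay summaries in thiolspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thiolspan)
```

`thiolspan` packages the statistics used in dietary-thiol aging studies of
*C. elegans*: gene-set overlap enrichment over a fixed gene universe, survival
curve analysis of worm cohorts, and bench-assay summaries. This vignette is
the package's account of those methods — the models, their assumptions, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not establish.

## Gene-set overlap: the representation factor

Two gene sets of sizes $n_1$ and $n_2$, drawn independently from a universe
of $N$ genes, share on average $E = n_1 n_2 / N$ genes. The representation
factor of an observed overlap $k$ is

$$\mathrm{RF} = \frac{k}{E} = \frac{k\,N}{n_1 n_2},$$

a pure effect-size measure: RF = 1 means exactly chance-level overlap.
Formatted output rounds RF to one decimal place, the precision at which such
values are customarily printed; full precision is retained in the object.

Under independence the overlap is $X \sim \mathrm{Hypergeometric}(N, n_1,
n_2)$, and significance is the upper tail $P(X \ge k)$. `hypergeom_tail_p()`
computes each probability mass term in log space from log-gamma binomial
coefficients and accumulates the tail with log-sum-exp. This matters because
realistic enrichments are far beyond double precision for naive factorial
ratios: the worked overlap of $k = 189$, $n_1 = 500$, $n_2 = 1382$,
$N = 20470$ has a tail probability of about $4\times 10^{-93}$. The
implementation is validated in the test suite against exact binomial
coefficient summation for every feasible $(N \le 60, n_1, n_2, k)$ to within
$10^{-12}$, and against an independent survival-function route at full scale.

`normal_approx_p()` reports the classical normal approximation
$z = (k - \mu - c)/\sigma$ with the hypergeometric mean
$\mu = n_1 n_2/N$ and variance
$\sigma^2 = n_1 n_2 (N-n_1)(N-n_2) / (N^2 (N-1))$. The continuity correction
$c = 0.5$ is on by default, standard practice when a discrete distribution is
approximated by a continuous one; a flag preserves the uncorrected variant.
Both p-values are always reported and labelled, with the exact tail as the
headline statistic: published overlap p-values of this kind have often come
from external web calculators whose tail convention is unstated, so the
package exposes a reproducible exact value alongside the named
approximation. Note a sharp limitation of the approximation: deep in the
tail it is off by many orders of magnitude (it is anti-conservative here),
and the discrepancy *grows* with $N$ at a fixed $k/\mu$ ratio — the normal
approximation converges to the exact tail only in the central regime (fixed
$z$, growing $N$), which is what the convergence property test checks.

When the variance is zero (e.g. one set is the whole universe) the normal
approximation degenerates; the package returns the point-mass tail (1 if
$k \le \mu$, else 0) with a warning.

The default universe size is 20470, the protein-coding gene count used for
*C. elegans* backgrounds; every function takes an explicit `N`, and the
pipelines record the resolved value in their JSON provenance. No
multiple-testing correction is applied across overlap reports: each report
is a single planned comparison, and raw p-values are the convention for this
statistic; `p.adjust()` composes naturally downstream if a user screens many
reference sets.

## Constructing gene sets from DE tables

A published ">k-fold" selection is interpreted as $|\log_2 \mathrm{FC}| >
\log_2 k$ with a **strict** inequality — strictness must be fixed one way or
the other for counts to be reproducible, and "greater than k-fold" reads as
strict. Direction (`up`, `down`, `both`) applies the sign; an optional
adjusted-p cutoff is available but **off by default**, because fold-change
set descriptions that state only a fold bound should reproduce from the fold
bound alone. Optional top-n truncation ranks the filtered genes
(|log2FC| descending, or p-value/padj ascending) with ties at the boundary
broken by lexicographic gene id, making set construction fully
deterministic.

Gene identifiers are canonicalized (whitespace trimmed, upper-cased) by
default before matching, because published worm gene lists freely mix
`sod-3`, `SOD-3` and WormBase IDs in different cases; `normalize = FALSE`
disables this for identifier schemes where case is meaningful.

## Lifespan curves and the Boltzmann sigmoid

Worm-level records (`experiment_id`, `condition`, `worm_id`, `event_day`,
`status`) use day 0 = L4 stage. Worms lost to matricidal internal hatching
(or other censoring-like events) are **removed from the denominator
entirely**, not right-censored: this matches the stated practice of
excluding such worms from lifespan calculations. A Kaplan-Meier mode
(`method = "km"`, via the survival package) is available for users who
prefer censoring-aware estimates, but it is not the default precisely
because the exclusion rule is the documented convention being implemented.
The two differ when exclusions are frequent and early; with the default
generator settings (5% exclusions) the difference is small.

The fraction-alive curve is fitted by Levenberg-Marquardt least squares
(minpack.lm) to the Boltzmann sigmoid

$$S(t) = A_2 + \frac{A_1 - A_2}{1 + e^{(t - x_0)/dx}}.$$

By default the asymptotes are pinned at $A_1 = 100$, $A_2 = 0$ — every worm
starts alive and, in a completed experiment, every worm dies — leaving the
inflection $x_0$ (days; equal to the median lifespan under pinned
asymptotes) and the slope scale $dx$ (days) free. Free-asymptote mode exists
for truncated experiments and solves $S(t) = 50$ for the median.
Initialization is deterministic and data-driven ($x_0$ from the point
nearest 50% survival; $dx$ from half the 25%-to-75% day span, clamped to at
least 0.5 d), so repeated fits are identical. Fits need at least four curve
points spanning both sides of 50% survival; all-alive and all-dead curves
are rejected as degenerate rather than silently extrapolated.

Composite curves **pool worms** across experiments before curve
construction, weighting each experiment by its worm count — the convention
implied when composite plots quote a single total n. Averaging per-experiment
curves instead would weight experiments equally; the pooled default is
recorded in the curve object.

`compare_conditions()` computes, per experiment shared between control and
treated arms, a lifespan statistic and the percent change
$100(\text{treated}-\text{control})/\text{control}$, then the mean and
sample SD ($m-1$ denominator) across the $m$ experiments. The reported
±SD is the spread **across experiments** (flagged as such in the output
metadata), not propagated fit uncertainty. The default per-experiment
statistic is the fitted median (lifespan claims are typically about the
median), while the paired two-tailed Student t-test is computed on
per-experiment **mean** lifespans (the convention for spreadsheet-paired
lifespan comparisons): $t = \bar d / (s_d/\sqrt m)$, $df = m - 1$. With
`stat = "mean"` the two coincide. Deaths are used at their recorded scoring
day with no interval-midpoint imputation, matching how plates are actually
scored.

## Bench-assay statistics

Stress survival is the alive/total percentage; replicate series are
summarized as mean ± SEM over the replicate fractions. The DTNB/glutathione
calibration is an ordinary least-squares line of A412 on concentration;
inversion floors at zero (negative thiol content is reported as 0 with a
warning, since it can only arise from blank-level noise) and divides by
protein mass. The reaction-volume factor between lysate aliquot and reported
per-mg amounts is protocol-specific and therefore a required user input
(default 1), not a guess. Group summaries use the box-plot convention —
median, quartile box, 5th/95th percentile whiskers, min/max/mean — with
percentiles by linear interpolation of order statistics (`quantile`
type 7, the spreadsheet and plotting-software default); the convention is
configurable and recorded in the output. t-tests default to Student's
pooled-variance form (matching spreadsheet practice for these assays), with
Welch by flag; the degenerate zero-variance-equal-means case returns
$t = 0$, $p = 1$ with a warning.

## Synthetic data: what the generators establish

`gen_overlap_sets()` plants an overlap **exactly**: set 1 is sampled
uniformly, set 2 takes `k_planted` members from inside set 1 and the rest
from outside, so the intersection equals `k_planted` by construction, not in
expectation. This makes the planted RF an exact oracle for the full
threshold-intersect-report path.

`gen_lifespan_cohort()` draws death times from a logistic distribution with
location $x_0$ and scale $dx$ — chosen deliberately so that the true
survival function is exactly the Boltzmann sigmoid the lifespan module fits,
making $(x_0, dx)$ recoverable parameters rather than approximations. Draws
are left-truncated at zero by resampling (clamping would put an atom at 0)
and rounded **up** to the next scoring day, because deaths are discovered at
plate scoring. A consequence worth noting: the recorded fraction alive *at a
scoring day* is an unbiased sample of the true survival there, but at times
between scoring days the recorded curve overstates survival; tests and fits
therefore evaluate on the scoring grid. Treatment acts multiplicatively on
the median ($x_0 \to x_0 \cdot \text{treatment\_factor}$); a Gompertz option
with matched median exists for misspecification testing. Default scenario
values — $x_0 = 15$ d, $dx = 2$ d, scoring every 2 d, 200 worms per arm,
three experiments, 5% internal-hatching exclusions — are typical of
well-powered worm lifespan experiments of this design.

Each generator seeds its own stream from the supplied seed (experiments use
seeds derived from a master seed), so outputs are bit-reproducible for a
fixed seed and R version.

What passing tests on these generators do **not** show: real lifespan data
are not exactly logistic (late-life hazards are closer to Gompertz), worms
are scored with occasional misses rather than on a perfect grid, exclusions
cluster in mid-life rather than occurring uniformly, and real DE effect
sizes are not a clean planted shift over an exchangeable null. The
generators validate the *analysis machinery* — estimator consistency,
exclusion accounting, planted-effect recovery — not the biological claims of
any particular study, whose worm-level raw data would be required.

## Problem sizes and tolerances used in the checks

The exact-tail equivalence property is verified exhaustively for all
feasible cases with $N \le 60$ (about a million tail evaluations) at
$10^{-12}$ absolute tolerance. Boltzmann recovery uses 50 replicate cohorts
of 200 worms (mean fitted $x_0$ required within 2% of truth) and a planted
0.90 treatment factor across 10 experiments (mean percent change required
within simulation standard error of −10%). These sizes give stable
statistics while keeping the full suite fast enough to run routinely.

## Known limitations

- The exact tail and RF assume a well-defined, common gene universe; if two
  compared lists were called against different annotation universes, $N$ is
  ambiguous and the RF shifts accordingly. The universe is therefore an
  explicit, recorded parameter everywhere.
- The exclusion-denominator rule discards information that a censoring-aware
  estimator would use; it is the documented field convention, and the KM
  mode exists for sensitivity analysis.
- Free-asymptote Boltzmann fits on heavily truncated curves can trade off
  $A_2$ against $dx$; the median is then reported from the fitted curve but
  its uncertainty is not propagated.
- The normal approximation to the hypergeometric tail is reported because it
  is named in the conventions this package audits, but it should not be used
  for inference on strong enrichments (see above).
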