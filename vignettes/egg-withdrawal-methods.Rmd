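---
title: "Methods: egg residue depletion and withdrawal-interval estimation"
author: "eggwdi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg residue depletion and withdrawal-interval estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggwdi)
```

## The problem

When a drug is prescribed extra-label to laying hens — ivermectin for mite
control is the motivating case — no tolerance or maximum residue limit
(MRL) exists for eggs, and the prescribing veterinarian must issue an
extended withdrawal interval (WDI): the time after the last dose before
eggs may enter the food supply. This package implements the quantitative
chain that produces such an estimate from egg residue-time data:
censoring-aware data handling, non-compartmental analysis (NCA) of per-hen
yolk profiles, Monte Carlo augmentation of sparse timepoints to regulatory
sample sizes, and three WDI estimators (half-life multiplier, FDA-style
99/95 tolerance limit, EMA-style 95/95 tolerance limit on the final seven
timepoints), plus a calibrated flock simulator so every stage is testable
without access to raw study data.

All concentrations are in ng/g (equivalently ppb); pipeline time is in
days since the **final** administered dose (input files carry study days
and are shifted on read); pharmacokinetic parameters are reported in
hours, the conventional unit, with explicit `hours_to_days()` /
`days_to_hours()` conversions so the two unit systems never mix silently.

## The synthetic laying flock

The generator (`simulate_flock()`) emulates a pilot-style depletion study:
8 hens receive 0.4 mg/kg topically on days 0 and 7, and every laid egg for
90 days is separated into yolk and white and assayed (LOD/LLOQ 0.03/0.075
ng/g in yolk, 0.01/0.025 ng/g in white).

**Kinetic model.** Each hen's latent yolk concentration is a superposition
of one Bateman term per dose,

$$C(t) = \sum_{i:\,d_i \le t} A\,\frac{k_a}{k_a - k_e}
  \left(e^{-k_e (t-d_i)} - e^{-k_a (t-d_i)}\right),$$

with absorption rate $k_a$ (1/day), elimination rate $k_e$ (1/day) and
amplitude $A$ (ng/g); $k_a > k_e$ by construction (the ratio, not the
rates, is drawn), so the terminal slope is always $-k_e$ and flip-flop
kinetics cannot arise. The typical-hen curve is calibrated numerically
(`calibrate_yolk_kinetics()`): $k_e = \ln 2 / 9.5$ d$^{-1}$ fixes a
9.5-day terminal half-life, and $k_a$ and $A$ are solved by root-finding
so the two-dose curve peaks 6.6 days after the final dose at 3.54 ng/g —
the study conditions the simulator reproduces. This yields
$k_a \approx 0.17$ d$^{-1}$, i.e. slow percutaneous absorption, and
residues that fall through the yolk LOD roughly 70–80 days after the final
dose.

**Population and noise.** Hen-level parameters are lognormal around the
calibrated geometric means with geometric SDs 1.15 ($k_a$), 1.25 ($k_e$)
and 1.2 ($A$); these dispersions are defaults chosen once to span the
reported between-hen ranges (half-life roughly 6–12 days, observed Cmax
roughly 2.5–5 ng/g) — no between-animal variances are published, so they
are stated assumptions, not estimates. Measured concentrations multiply
the latent curve by mean-one lognormal noise combining an analytical CV of
2.3% (the assay's intra-assay variation) with a biological CV of 25%
(egg-to-egg deposition variability; again a stated default). Egg white is
the yolk curve scaled by a partition fraction of 0.0025 with its own noise
draw, which leaves all but a handful of white records below their LOD —
the qualitative behaviour the analysis must cope with.

**Observed-Cmax calibration.** The observed Cmax of a hen is the maximum
of several noisy measurements near the peak, which systematically exceeds
the latent peak (by about 25% at these noise levels). Because the study
statistic being emulated is the *observed* geometric-mean Cmax, the
default configuration rescales $A$ once by that bias factor, estimated
from a 400-hen simulation at a fixed internal seed; observed Cmax is
exactly linear in $A$, so a single rescaling suffices
(`calibrate_observed_cmax = TRUE`). The deterministic solver is left
untouched.

**Laying process.** Inter-egg gaps are $1 + \mathrm{Gamma}$ distributed
(1 day is the physiological floor): each hen's mean excess gap is drawn
lognormally (between-hen geometric SD 1.3) around an arithmetic flock mean
of 0.52 days, giving the target flock-mean interval of 1.52 days, and
within-hen gaps use gamma shape 0.4, whose heavy tail produces the
occasional multi-day laying pause. One hen per flock is assigned a
cease-lay day uniform on days 40–60. Collection for a hen also stops after
three consecutive eggs below the LOD in both matrices, mirroring the
study's stopping rule.

**What the generator does not emulate.** Eggs are assigned the single
collection time — there is no yolk-maturation back-dating, no
multi-follicle deposition model, no plasma compartment, and no
storage-time assay drift. Passing tests therefore demonstrate that the
*analysis machinery* is correct under a plausible data-generating process
with the study's design, sampling density and censoring; they do not
validate the biological model of yolk deposition itself.

## Non-compartmental analysis

`nca()` works per hen on the post-final-dose profile of quantifiable
records (values in [LOD, LLOQ) are retained as reported but flagged; only
below-LOD records are excluded — the stricter policy is available via
`apply_blq_policy(..., "exclude_below_lloq")`).

- **Cmax/Tmax** are read directly from the data, ties to the earliest
  time.
- **$\lambda_z$** comes from the *best-fit* rule: among candidate sets of
  the last $k$ points strictly after Tmax ($k = 3$ up to all post-peak
  points; the Tmax point is excluded to avoid absorption-phase
  contamination), the set maximising adjusted $R^2$ wins. Ties are broken
  toward more points, but only numerical ties (within $10^{-9}$): a looser
  tie band would pull near-peak curvature into the terminal set and bias
  $\lambda_z$ on clean data — with the strict rule, noise-free single-hen
  recovery of $k_e$ is within 1%. Candidate sets with non-negative slope
  are discarded; `t_half = ln 2 / lambda_z` holds exactly for every
  result.
- **AUC** uses the linear trapezoid over observed points everywhere (no
  log-down rule), extrapolated by $C_\mathrm{last}/\lambda_z$.
- The flock summary is the geometric mean with (min, max) range over hens
  with a valid terminal fit. The half-life/rate-constant identity is
  enforced throughout; the package never reports a $\lambda_z$
  inconsistent with its own half-life.

## Timepoint augmentation

Regulatory tolerance-limit methods expect at least 10 values per
timepoint; a small flock laying irregularly cannot provide that.
`summarize_timepoints()` bins quantifiable yolk records to integer days
since the final dose (collection is daily, so the nearest-day bin is the
sampling grid; same-hen eggs in one bin both count) and keeps bins with at
least 5 observations. `augment_timepoints()` then draws the shortfall to
10 values per bin from $\mathcal{N}(\bar{x}_j, s_j)$ **truncated below at
the LOD** by rejection sampling. The truncation is a deliberate choice:
sub-LOD values are excluded from WDI calculations anyway, so rejecting
sub-LOD draws implements that exclusion at source rather than generating
and discarding them downstream; a plain normal would also occasionally
emit negative concentrations. Observed values pass through unchanged and
first, so augmented datasets are reproducible byte-for-byte under a fixed
seed. Degenerate bins ($s_j = 0$) augment to constant draws; a bin mean
below the LOD is an error, since such a bin cannot survive the censoring
policy.

## Withdrawal-interval estimators

**Half-life multiplier.** `wdi_hlm()` returns $10 \times t_{1/2}$
converted to days — the time for >99% depletion under first-order
elimination — rounded up to the next whole day, as all WDIs are (WDIs are
issued in 24-h increments, never rounded down).

**Regression tolerance limits.** Both regulatory methods fit ordinary
least squares to $\ln C$ vs time (`depletion_fit()`) and compute the
one-sided upper tolerance limit

$$\mathrm{UTL}(t) = \hat{y}(t) + K(t)\,s, \qquad
  K(t) = \frac{t_{\,n-2,\; z_P \sqrt{n^*(t)}}^{(\mathrm{conf})}}{\sqrt{n^*(t)}},
  \qquad
  n^*(t) = \left(\frac{1}{n} + \frac{(t-\bar{x})^2}{S_{xx}}\right)^{-1},$$

where $z_P$ is the standard-normal $P$-quantile and the numerator is a
noncentral-$t$ quantile. Under the normal-errors model this limit exceeds
the true $P$-quantile of the residue distribution at each fixed $t$ with
probability exactly equal to the confidence level; the implementation is
validated against a brute-force coverage simulation (10,000 regressions
from a known line in the unit tests, 1,000 in the acceptance checks)
rather than against any proprietary worksheet. With $s = 0$ the limit
collapses onto the fitted line, so all tolerance-limit WDIs equal the
deterministic line-crossing time — a useful exactness check.

The WDI is the earliest $t$ with $\mathrm{UTL}(t) \le \ln(\text{limit})$,
located on a 0.01-day grid (raw WDIs are conventionally reported to 0.1
day) and refined by bisection between the bracketing grid points; if the
limit is never reached inside the search window (365 days by default) the
estimator fails loudly, naming the window end.

The two agency styles differ in percentile and, crucially, in window —
encoded as separately configurable policies because the window is what
drives their divergence on slowly depleting residues:

- `wdi_fda()`: $P = 0.99$, confidence 0.95, **all** elimination-phase
  timepoints (`run_pipeline()` takes the phase to start at the timepoint
  of peak mean concentration).
- `wdi_ema()`: $P = 0.95$, confidence 0.95, the **final seven**
  timepoints only. On a long shallow tail hovering near the limit, the
  restricted window overstates the terminal persistence, and the
  nominally less conservative 95/95 method can return the *longer* WDI —
  an inversion the test suite reproduces with a constructed two-slope
  fixture.

On identical data and window, the 99th-percentile WDI is never shorter
than the 95th, and a lower residue limit never shortens a WDI; both
orderings are asserted as properties.

**Residue limits.** With no MRL/tolerance in force, `residue_limit()`
encodes the substitution rules: the assay LOD (US practice) or twice the
LLOQ (EU practice), alongside explicit MRLs. `compute_par()` provides the
ADI-based provisionally-acceptable-residue alternative,
$\mathrm{PAR} = \mathrm{ADI} \times \mathrm{bw} \times f / \mathrm{cons}$;
with ADI 5 µg/kg/d, 60 kg bodyweight, 20% egg partitioning and 0.1 kg/d
consumption this is 600 ppb.

**EMA data checks.** On its restricted window `wdi_ema()` runs a
lack-of-fit F test (linear model against per-timepoint means) and
Bartlett's variance-homogeneity test, both at $\alpha = 0.05$. Failures
warn rather than abort — small extra-label datasets rarely satisfy
approval-grade assumptions, and an estimate with a recorded caveat is more
useful than none — but `strict = TRUE` turns them into errors.

## Orchestration and reproducibility

`run_pipeline()` chains simulate/read → censoring policy → NCA →
elimination-phase timepoints → augmentation → WDI methods, writing
`flock.csv`, `nca.csv`, `augmented.csv`, `wdi.json` and `report.md` with
units in every header. A single master seed fans out to per-stage child
seeds (`seed + stage index`), so a stage re-run in isolation reproduces
its in-pipeline output, and two runs with the same configuration are
bit-identical. Flock CSVs round-trip exactly: concentrations are written
at full double precision and censored records as `BLOD`/`BLOQ` tokens (a
`BLOQ` token carries no number, so such records are excluded from numeric
analyses).

## Numerical choices and problem sizes

Degenerate and edge inputs are handled explicitly: empty series, fewer
than three post-peak points, all-rising candidates, singular designs,
zero residual variance, zero-SD bins, sub-LOD bin means, and
non-crossing tolerance limits each produce a specific error or a
documented exact behaviour. The test suite sizes its simulations to run
in a few minutes on one CPU: 10,000 replicates for the tolerance-factor
coverage oracle (1,000 in the acceptance variant), 500 for the
slope-recovery check, 200 single-hen replicates for noisy $\lambda_z$
recovery, and 200 replicate flocks for the laying-cadence check; these
sizes are the package's own choices and give Monte Carlo error well
inside every asserted margin.

## Limitations

The estimators assume log-linear depletion with homoscedastic lognormal
scatter; the EMA checks flag but cannot repair violations. Augmentation
reuses each timepoint's own mean and SD, so it widens no uncertainty
beyond the observed scatter and cannot substitute for real sample size.
The simulator's dispersions and partition fraction are assumptions, and
WDIs derived from synthetic flocks characterise the methods, not any real
drug-species combination. Hen-level kinetics are dose-proportional and
time-invariant; egg-white profiles are not modelled mechanistically.
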