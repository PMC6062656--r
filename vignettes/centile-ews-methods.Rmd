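---
title: "Centile-based early warning scores: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centile-based early warning scores: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cews)
```

## The problem

Track-and-trigger systems on general hospital wards summarise a patient's
vital signs into a single integer early warning score (EWS): each vital sign
contributes a sub-score of 0--3 depending on which band of values it falls
in, a reduced conscious level (anything below Alert on the AVPU scale) adds
3, and some systems add 2 when the patient is on any supplemental oxygen.
The aggregate score drives escalation decisions. Most published systems
chose their band boundaries by clinical consensus or by supervised
optimisation against recorded outcomes.

The centile-based alternative implemented here is *unsupervised*: it treats
values in the tails of the ward population's vital-sign distribution as
abnormal by definition. Thresholds are placed at fixed centiles of a
smoothed estimate of each vital sign's distribution, so a candidate EWS can
be derived from any sufficiently large observation database without outcome
labels, and re-derived for sub-populations (a COPD ward, paediatrics)
by swapping the database.

## The derivation model

For a vital sign with samples $x_1, \dots, x_n$, the distribution estimate
is a kernel density estimate with Gaussian kernels and the
normal-approximation ("rule of thumb") bandwidth

$$ h = 1.06\,\hat\sigma\,n^{-1/5}, $$

where $\hat\sigma$ is the sample standard deviation. The smoothed CDF is the
equal-weight Gaussian-mixture CDF

$$ P(x) = \frac1n \sum_{i=1}^n \Phi\!\left(\frac{x - x_i}{h}\right), $$

and thresholds are read off at fixed centiles of $P$: the 10th, 5th and 1st
centiles bound the lower score-1/2/3 bands, and the 90th, 95th and 99th the
upper ones. Two variables deviate: SpO$_2$ is one-sided (only low values are
abnormal; thresholds at the 20th, 10th and 2nd centiles, values at or above
the 20th-centile threshold score 0), and temperature, whose centiles sit too
close together for six distinct integer cutoffs, has no score-2 bands
(thresholds at the 10th/1st and 90th/99th centiles, at 0.1 °C resolution).

`kde_bandwidth()`, `smoothed_cdf()`, `invert_centile()` and
`derive_band_table()` implement these steps; `derive_ews()` assembles a full
definition. Derivation is deterministic: no randomness enters after the data.

### Numerical choices

* **CDF grid.** $P$ is evaluated on a 4096-point regular grid spanning the
  sample range extended by $4h$ on both sides, so the unresolved tail mass is
  below $\Phi(-4) \approx 3\times10^{-5}$ and all derivation centiles are
  interior. Inversion interpolates linearly between grid points; round-trip
  error $|P(P^{-1}(p)) - p|$ is at the $10^{-9}$ level in tests.
* **Large samples.** For $n > 8192$ the samples are linear-binned onto the
  evaluation grid and the mixture CDF is computed by FFT convolution of the
  bin weights with the kernel CDF. Binning error is $O((\Delta/h)^2)$ with
  grid step $\Delta \ll h$; exact and binned paths agree to $10^{-6}$ in sup
  norm in tests. Small samples use the exact mixture sum.
* **$\hat\sigma$.** The $n-1$ (sample) denominator, switchable to $n$ via
  `sd_denominator`; the two are indistinguishable at derivation sample sizes.
* **Rounding.** "The integer value that corresponds to" a centile is
  implemented as round-half-away-from-zero at the variable's charting
  resolution (1 for most vitals, 0.1 °C for temperature). Floor, ceiling and
  banker's rounding were equally defensible readings; nearest-value rounding
  is symmetric and is applied uniformly.
* **Collisions.** If two rounded thresholds coincide (a band would be
  empty), `derive_band_table()` fails listing the colliding centiles rather
  than silently merging bands. This happens for genuinely tight
  distributions and is a property of the data, not a bug to be smoothed
  over.
* **Heaped data.** Manually charted values show digit preference (spiky
  histograms). No dithering is applied: the KDE itself is the smoothing
  mechanism, which is the point of the method.

### Band boundary convention

Bands are stored with their printed inclusive endpoints ("43--49" means
$43 \le x \le 49$) at the charting resolution; internally the partition is
half-open on a grid shifted by half the resolution, so a monitor reading of
104.5 falls in the band *above* one ending at 104 instead of being rejected.
Every admissible value lands in exactly one band (asserted by exhaustive
grid scans against a brute-force interval-membership oracle).

One published cell needed a decision: the manual-CEWS respiratory-rate row
prints overlapping score-2/score-1 cells ("8--11" then "11--12"). Under the
half-open centile rule — a value *at* the 5th-centile threshold has left the
score-2 region — RR = 11 scores 1, and the score-2 band is stored as 8--10.
The shipped definition documents this; tests assert it explicitly rather
than letting either reading pass.

The AVPU row of the published chart does not align its columns; A→0 and
V/P/U→3 is the reading consistent with NEWS and is used for both shipped
CEWS definitions.

## Preprocessing

Admission-level rules (adults only, palliative-medicine admissions excluded,
same-calendar-day live discharges excluded, at least one complete
observation set) are applied by `filter_admissions()` with per-rule counts.
Observation sets with more than two missing measurements, or any
physiologically implausible value, are dropped; the remainder are completed
by development-population mean imputation (`impute_observations()`). Because
the means of the development data necessarily sit inside the score-0 bands
derived from the same data, imputation is score-neutral: an imputed variable
contributes 0 to the aggregate score. This is asserted per variable in the
tests, both for the published development means and for self-derived
definitions on synthetic data.

Two under-specified points are explicit, switchable decisions rather than
silent guesses: the plausibility ranges (HR 10--300, RR 1--80, SBP 30--300,
T 25--45, SpO$_2$ 10--100; deliberately permissive, catching only
data-entry errors) and whether AVPU and the oxygen flag count as
"measurements" in the missingness tally (default: they do; missing AVPU
imputes to "A" and a missing oxygen flag to `FALSE`, the modal values).

## Outcome labelling and evaluation

The composite outcome is the first occurrence of cardiac arrest,
unanticipated ICU admission, or death; observation sets at or after the
first event are excluded, and a retained observation is positive when the
first event falls in the half-open window $(t_{obs}, t_{obs} + T]$ hours.
The window's right edge is inclusive by decision (the source is silent);
simultaneous events break ties deterministically (death > cardiac arrest >
unanticipated ICU), which can matter only for individual-outcome analyses.

Discrimination is summarised by the AUC, computed by the trapezoidal rule
over the discrete integer score support — which, with whole tied-score
groups contributing single segments, equals the mid-rank Mann--Whitney
concordance $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$ exactly (asserted against
an $O(n^2)$ oracle to $10^{-10}$) — and by the area under the
precision-recall curve using the step-wise average-precision convention
(trapezoidal PR interpolation is optimistically biased and is not used).
AUC confidence intervals use the DeLong variance estimate; AUC-PR intervals
use a seeded stratified bootstrap (2000 resamples by default), which also
cross-checks DeLong. The source does not state its CI method or tie
handling; both are documented decisions here.

`substitution_analysis()` quantifies which vital sign drives a performance
difference between two systems: each variable's band table is swapped in
from the donor in turn and the relative AUC change
$(\mathrm{AUC}_i - \mathrm{AUC}_{base})/\mathrm{AUC}_{base} \times 100\,\%$
reported. Identity substitution gives exactly 0, as does substituting a
variable whose tables are identical in both systems (SpO$_2$ for the two
shipped CEWS definitions).

## The synthetic cohort: what it does and does not establish

No public ward database exists for this kind of data, so `generate_cohort()`
stands in. Its stated world: marginals matched to published summary
statistics of charted ward observations (HR median 82, IQR 71--93; RR
17 (16--18); SBP 123 (110--138); T 36.3 (36.0--36.7); SpO$_2$ 97 (95--98);
98.2% Alert; 17.8% on oxygen), observations roughly 6-hourly, and a
composite-event prevalence targeted at 7% of admissions via a calibrated
logistic intercept on a latent per-admission severity $s \sim \mathrm{Exp}(1)$.
Vitals are shifted towards their deteriorating tails in Gaussian-copula
space by $\delta \cdot s \cdot w(t)$, where the proximity weight $w(t)$
rises towards 1 as an observation approaches the admission's event
(time constant 18 h, floor 0.3), so scores discriminate best at short
horizons — the mechanism behind the qualitative property that AUC declines
as the horizon grows from 12 to 48 h. With $\delta = 0$ vitals are
independent of outcomes and any EWS has AUC 0.5 by construction.

Distribution families are restricted to those with exact quantile functions
(uniform, truncated normal, and a truncated two-component normal mixture
whose closed-form CDF is inverted by monotone bisection to ~$10^{-12}$), so
threshold-recovery tests compare derived thresholds against the generator's
own truth rather than against empirical quantiles. Respiratory rate uses the
mixture family: a single normal matched to the tight printed IQR of 2
breaths/min places neighbouring centiles within the same integer — the
derivation then correctly refuses with a collision error — whereas charted
RR pairs that tight bulk with heavy tails reaching the high twenties, which
the 80/20 mixture reproduces.

Honest limits of a green synthetic test: the generator makes no attempt at
physiological time-series dynamics, inter-vital correlation beyond the
shared severity factor, case-mix structure, or the true shapes of charted
densities (digit-preference heaping is available as a toggle but off by
default). Recovery and discrimination tests therefore establish that the
*machinery* is correct — thresholds equal known quantiles, scores behave,
labelling windows nest, effect size moves AUC the right way — not that any
particular published AUC is reproduced; the published validation AUCs
belong to a hospital dataset this package cannot access. Cohort medians sit
1--4 units towards the deteriorating tails of the marginal parameters
because sick admissions are part of the cohort; that too mirrors how the
printed summary statistics arise.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| bandwidth rule | $1.06\hat\sigma n^{-1/5}$ | the stated normal-approximation rule; no cross-validated selectors |
| CDF grid | 4096 points, $\pm 4h$ | sub-resolution inversion accuracy at negligible cost |
| rounding | half away from zero, charting resolution | symmetric; matches printed integer/0.1 °C thresholds |
| horizons $T$ | 12, 24, 48 h | the three reported horizons; 24 h is the headline |
| oxygen increment | 2 | the published additional score for any oxygen support |
| plausibility ranges | wide (see above) | catch charting errors only, not outliers |
| max missing per set | 2 | sets with 3+ missing measurements are dropped |
| bootstrap | 2000 resamples, seeded | stable 95% percentile intervals, reproducible |
| prevalence target | 0.07 | reported fraction of admissions with the composite outcome |
| effect size $\delta$ | 1.0 | gives AUCs in the 0.8--0.9 range typical of published EWS validation |

## Known limitations

* Thresholds adjacent to a hard support boundary inherit a boundary bias
  from the Gaussian kernel (mass spills past the boundary); on
  Uniform(0, 100) at $n = 10^6$ the 1st-centile threshold derives to 0
  rather than 1, within the method's own ±1 behaviour, while interior
  centiles are exact. A boundary-corrected kernel is out of scope.
* Repeated observation sets from one admission are treated as independent in
  evaluation, the standard (and standardly criticised) convention for EWS
  validation; DeLong intervals are accordingly slightly anti-conservative
  under within-admission correlation.
* The 21 other published EWS systems and decision-tree comparators are not
  encoded; the config schema expresses any band-based system, and NEWS ships
  as the worked comparator.
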