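---
title: "Methods: proportion-index analysis of looking-while-listening data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proportion-index analysis of looking-while-listening data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design and the statistic

In a looking-while-listening (LWL) task an infant sees two pictures side by
side while one of them is named; comprehension is inferred from preferential
fixation of the named picture. The design analysed here uses 14 *yoked*
stimulus pairs: each pair is shown twice, once per experiment half, each
member named once, with sides constant within an infant and counterbalanced
across infants — 28 trials in total. Gaze is sampled at 60 Hz from −1,000 ms
(picture preview) to 7,000 ms after picture onset, and each sample is
classified as target AOI, distractor AOI, other on-screen, or
off-screen/invalid.

The core statistic is the **proportion index (PI)** of a yoked pair,

$$\mathrm{PI} = p_1 + p_2 - 1,$$

where $p_1, p_2$ are the two trials' target-looking proportions over the
window of interest (368–3,505 ms after the acoustic onset of the target
word), with the **AOI denominator** $p = n_\text{target} / (n_\text{target} +
n_\text{distractor})$. PI ranges from −1 (consistent distractor preference)
through 0 (chance) to +1 (consistent target preference). Under the AOI-only
denominator the index is *arithmetically redundant* in the yoked design:
anchoring on either image of the pair gives exactly the same number, since
looking at image A when named minus looking at A when distractor is
$p_1 - (1 - p_2)$. This exactness is a package invariant and a test; it is
the reason the AOI denominator was chosen over an all-on-screen denominator,
for which the redundancy would hold only approximately.

PI values aggregate two ways: **PI-by-infant** (unweighted mean over an
infant's pairs) and **PI-by-item** (unweighted mean over infants for one
pair).

## Exclusion rules

* *Trials*: discarded when the infant looked at the screen (any on-screen
  label) for less than 12.5 % of the samples in 0–7,000 ms. The criterion is
  a strict "less than"; exactly 12.5 % is retained. The −1,000 ms preview is
  not part of the denominator — "during the trial" is read as the
  stimulus-presentation period. The original criterion's treatment of the
  preview second and of background looks is not documented; both choices are
  flagged here as reconstructions, justified by the redundancy property
  above.
* *Pairs*: a pair yields a PI only when **both** trials survive with a
  defined proportion; single-trial pairs are dropped and logged.
* *Infants*: excluded when fewer than 4 of the 14 pairs are computable
  (exactly 4 retained).
* *Optionally* (`rare_word_exclusion`), per infant, pairs where either word
  was rated "rarely heard" (Likert 1) are removed before analysis.

# Inference battery

All location tests are nonparametric: a two-sided Wilcoxon signed-rank test
against zero (exact, via the signed-rank distribution, when fewer than 50
nonzero deviations and no ties; otherwise the tie- and
continuity-corrected normal approximation), with a Hodges–Lehmann 95 %
interval and pseudomedian. How the original interval was computed is not
documented; Hodges–Lehmann inversion is the standard companion of the
signed-rank test and is adopted here, labelled as a reconstruction. Group
comparisons use Kruskal–Wallis; associations use Pearson correlations,
one-sided where the hypothesis is directional.

## Bayes factors

Two default-prior Bayes factors are implemented by one-dimensional
quadrature (`stats::integrate`, absolute tolerance 10⁻¹²; each result
carries a numerical error estimate, and the test suite checks both
integrators against an independent dense-grid oracle to < 0.5 % relative
error):

* **One-sample JZS**: Cauchy prior with scale $\sqrt{2}/2$ on the
  standardised effect size; the marginal likelihood is the noncentral-t
  density integrated against the prior. It depends on the data only through
  $(t, n)$, so published results can be recomputed from printed summaries
  ($t = d\sqrt{n}$).
* **Correlation**: stretched-beta prior on $\rho$ with scale $\kappa = 1/3$
  (density $\propto (1-\rho^2)^{1/\kappa - 1}$ on $(-1, 1)$), integrated
  against the exact sampling density of the observed $r$ (evaluated with a
  Gauss hypergeometric series), depending on the data only through
  $(r, n)$.

`bf01` is the evidence for the null over the alternative; labels follow the
standard bands (1–3 anecdotal, 3–10 moderate, 10–30 strong, 30–100 very
strong, > 100 extreme) on $\max(\mathrm{BF}_{01}, 1/\mathrm{BF}_{01})$.

**Directional convention.** For a directional alternative the reference
workflow's two-model output reports, next to the interval-restricted
alternative, the Bayes factor of the *complement-direction* model against
the null, and it is this second quantity that LWL applications of the
workflow print as their directional "BF01". The package follows that
reporting convention: for `direction = "POSITIVE"` the returned `bf01` is
the Bayes factor of the $\rho < 0$ (or $\delta < 0$) model versus the null —
for a symmetric prior exactly $2\,\mathrm{BF}_{10}^{\text{two-sided}} -
\mathrm{BF}_{10}^{+}$ — while the truncated-and-renormalised directional
$\mathrm{BF}_{10}^{+}$ is returned alongside as `bf10_directional`. Both
conventions are therefore available, and the prior-averaging identity
$(\mathrm{BF}_{10}^{+} + \mathrm{BF}_{10}^{-})/2 =
\mathrm{BF}_{10}^{\text{two-sided}}$ is a tested invariant.

# Cluster-based permutation test

Whether target fixation deviates from chance anywhere in 0–7,000 ms is
tested on 50 ms bins (each pooling 3 samples per trial at 60 Hz; every
reported cluster boundary is then a 50 ms multiple). Per participant and
bin, the AOI-denominator proportion is pooled over retained trials,
transformed as $y = \arcsin\sqrt{p}$ (variance stabilisation; chance maps
to $\pi/4$ exactly), and the deviation $y - \arcsin\sqrt{0.5}$ is tested
against zero with a one-sample t per bin — algebraically identical to the
paired test against a constant chance dataset, since subtracting a constant
makes the two formulations the same statistic. Bins with fewer than two
participants or zero variance are skipped; empty bins are missing, not
zero, and break cluster adjacency.

Clusters are maximal runs of adjacent same-sign bins with $|t| > 2.02$ (the
threshold is a configuration value, not a constant; 2.02 is approximately
the two-sided t critical value near 40 degrees of freedom). The cluster
mass is the sum of its t statistics. The null distribution of the maximum
absolute mass is built from 1,000 resamples; each resample flips the sign
of every participant's *entire* deviation series with probability 1/2 —
the standard exchangeability argument for a one-sample test, which
preserves within-participant temporal autocorrelation. A cluster's p-value
is the fraction of resamples whose maximum |mass| reaches its |mass|
(`b/B`; an `(b+1)/(B+1)` mode is available), with `p < 0.05` called
significant; one null serves both signs. The resampling scheme behind the
original "bootstrapped" analysis is not described; sign-flipping is the
default here and a participant-resampling bootstrap (centred at the
observed means) is provided behind `mode = "bootstrap"`.

# The synthetic-data generator

Every stage is testable without participant data because the generator
produces gaze, questionnaires and CHAT transcripts with known ground truth.
Looking is a two-state (target/distractor) first-order dwell chain at the
sample level: with probability `stay_prob` (default 0.95, i.e. mean dwells
of ~333 ms) the gaze stays put. Naming-locked bias enters through the
chain's **stationary distribution**: after `target_onset + latency`
(truncated-normal latency, default 300 ± 100 ms, lower bound 0 because
saccade latencies are positive) the stationary target probability becomes
$0.5 + \delta_{ij}$ with

$$\delta_{ij} = \mathrm{clamp}(\delta + u_i + \beta\,\Delta_j), \qquad
u_i \sim N(0, \tau^2),$$

where $\Delta_j$ is pair $j$'s latent exposure imbalance in Likert points.
Modelling bias through the stationary distribution rather than per-sample
independence preserves dwell-time autocorrelation — with independent
samples the cluster test's mass variance would be understated and its
type-I calibration meaningless. Off-screen excursions are a superimposed
two-state process (hazards `p_off`/`p_return`) independent of the AOI
state, so missingness is ignorable for the PI. "Fussy" trials (probability
`fuss_prob`) use inflated off-screen hazards and typically fail the 12.5 %
filter. One sample is emitted as `ONSCREEN_OTHER` whenever the gaze
switches AOI, exercising the AOI-denominator semantics.

Defaults mirror the reference study's conditions: 14 infants per age group
(42 total; ages drawn per group using 30-day months, groups `<8`, `8–<11`,
`≥11` months), 14 pairs / 28 trials, 481 samples per trial over −1,000 to
7,000 ms, naming onset ~3,000 ms (the target word ends a carrier phrase).
No empirical dwell-time or fussiness distributions are published for this
paradigm, so `stay_prob`, the off-screen hazards and `fuss_prob` are
plausible placeholders, clearly so labelled; conclusions from passing tests
transfer to real data only to the extent that real gaze behaves like a
dwell chain with ignorable missingness — fixation parsing, drift, pixel
coordinates and saccade kinematics are deliberately out of scope.

Questionnaire ratings are the latent exposure plus $N(0, 0.8)$ noise,
rounded and clamped to 1–5; understanding status is a logistic function of
age and exposure (placeholder constants, documented in the code). CHAT
fixtures are minimal but structurally valid documents whose `@ID` header
carries the child age; corpus counting is case-insensitive exact
orthographic matching (no lemmatisation or compound splitting — the
original's morphological handling is undocumented, so the simplest
reproducible rule is used), over all speakers except the target child, in
transcripts of children younger than 33 months.

## The analytic oracle

For homogeneous configurations ($\tau = \beta = 0$) `expected_pi()` gives
the expected PI in closed form up to a 1 ms quadrature over the latency
distribution: $E[\mathrm{PI}] = 2\delta w$, where $w$ accounts for (i) the
fraction of window samples after bias onset, (ii) geometric relaxation of
the chain toward the biased stationary distribution (eigenvalue
$1 - 2(1-\text{stay\_prob})$ per sample), and (iii) the removal of
transition samples from the AOI counts. It agrees with an independent
brute-force chain re-simulation to within ±0.01, and the full pipeline
recovers it from simulated datasets to within ±0.02 at 200 infants.

# Problem sizes and numerical choices

The test suite's statistical checks run at deliberately chosen scales: null
calibration of the cluster test uses 200 datasets of 24 infants with 200
resamples each (the expected any-cluster false-positive rate is ~0.05;
the acceptance band 0.02–0.09 is the binomial 95 % band); signed-rank
p-value uniformity uses 2,000 replicates of n = 30; parameter recovery uses
one 201-infant dataset and 50 replicates of 60 infants for the item effect
($\beta = 0.04$, chosen once to put the induced imbalance–PI-by-item
correlation in the range reported for the parental measure). Ties in the
signed-rank test get midranks with tie-corrected variance; zeros are
dropped before ranking (the classical treatment — the original is silent on
both). Permutation p-values use the raw `b/B` count to match common
package behaviour. All stochastic steps take explicit seeds and are
byte-reproducible.

# Known limitations

* The generator's bias is sustained from naming onward (optionally
  time-limited via `bias_duration_ms`); real post-naming effects wax and
  wane smoothly.
* Item effects enter symmetrically for both pair members; an
  exclusion-strategy mechanism (knowing only the frequent word) would be
  asymmetric and is not modelled.
* The CHAT parser covers the header/tier subset needed for counting, not
  the full CHAT specification (no dependent tiers, no disfluency codes).
* Corpus totals from any real CHILDES snapshot are database-version
  dependent and are not a reproduction target.
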