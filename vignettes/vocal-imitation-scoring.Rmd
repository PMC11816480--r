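---
title: "Scoring vocal imitation of speech and song: metrics, models, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring vocal imitation of speech and song}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmatch)
```

## The measurement problem

In a vocal imitation task a participant hears a short model utterance — a
spoken sentence or its sung counterpart — and reproduces its pitch and
timing as exactly as they can. Imitative accuracy is then a *comparison*
between the model and the imitation, syllable by syllable: analysing the
imitated recordings alone confounds a participant's habitual voice with
their ability to match a target. `vocalmatch` implements that comparison
for syllable-aligned prosody data: each utterance is reduced to one record
per syllable rhyme (the vowel-plus-coda stretch) holding its onset time,
its duration, and the median fundamental frequency (F0) over the rhyme,
and each trial is scored on seven metrics.

Annotations arrive either as Praat TextGrid interval tiers plus a pitch
track (PitchTier or a frame-level `time_s,f0_hz` CSV), the carriers
produced by ProsodyPro-style workflows, or as a flat syllable table CSV.
Pitch samples are assigned to rhymes by half-open windows `[start, end)` so
a sample on a boundary is never counted twice; empty-label intervals are
treated as non-rhyme material and dropped. F0 tracking itself is out of
scope — the package consumes annotations, it does not make them.

## The seven metrics

All pitch arithmetic is done in cents: 100 cents is one equal-tempered
semitone, 1200 an octave, and the deviation of an imitated frequency
$f_i$ from a model frequency $f_m$ is $1200\,\log_2(f_i/f_m)$. Production
and perception of pitch are ratio-scaled, so errors are symmetric on this
log scale where they are not in Hz.

**Octave correction.** Creaky phonation commonly halves the apparent F0 of
a rhyme, displacing it by an octave without any musical error by the
speaker. Before any metric is computed, each imitated F0 is scaled by the
integer power of two that brings its deviation from the model into
$(-600, +600]$ cents; a deviation of more than half an octave is thus
folded (e.g. 700 cents sharp becomes 500 cents flat, the `12 − x`
semitone rule), while exactly 600 cents — not *more than* half an octave —
is left alone. The folding is idempotent and every corrected syllable is
flagged, so the adjustment rate is itself a data-quality diagnostic
(`octave_flags` in the trial table). Intervals are computed from the
*corrected* pitches; an uncorrected interval would penalize a single
creak-induced octave drop twice, once in each flanking interval. A
`correct_octave = FALSE` switch preserves the uncorrected variant.

Per trial the package reports:

1. **Absolute pitch deviation (cents)** — mean over syllables of the
   absolute corrected deviation. Sensitive to register and to per-syllable
   accuracy.
2. **Relative pitch deviation (cents)** — pitch intervals (cents between
   consecutive syllables) are compared by magnitude,
   $|\,|I_i| - |I_m|\,|$, and averaged. Invariant under transposition: a
   singer who is uniformly a third too low but preserves every interval
   scores zero.
3. **Pitch contour errors (count)** — each interval is classified up /
   down / level with a ±50-cent threshold (inclusive: ±50 is already a
   direction); an error is a classification mismatch.
4. **Pitch interval errors (count)** — intervals whose magnitude differs
   from the model's by 100 cents or more, direction ignored. The threshold
   is inclusive, mirroring the explicit "50 cents or more" contour rule.
5. **Absolute duration difference (ms)** — mean absolute difference of
   rhyme durations.
6. **Relative duration difference (ms)** — mean absolute difference of
   interonset intervals (IOIs, onset-to-onset gaps; an $n$-syllable
   utterance has $n-1$ of them, the final offset never enters). Invariant
   to a constant latency shift of the whole imitation.
7. **Time errors (count)** — syllables whose duration deviates from the
   model's by strictly more than 25% of the *model* duration, the natural
   reference for "longer or shorter than the model syllable". Rhyme
   duration, not IOI, is compared, paralleling the absolute-duration
   definition.

**Missing F0.** A fully creaky or unvoiced rhyme yields no median F0. The
original workflow hand-corrected pulse marks; that is not automatable, so
here a missing F0 propagates: the syllable is excluded from the absolute
pitch mean and both flanking intervals are excluded from the three
interval-based metrics, never imputed. `n_scoreable_syllables` is emitted
per trial so analysts can filter. Duration metrics are unaffected.
A trial whose imitation has a different syllable count than its model
(inserted or dropped syllables) is not force-aligned; it is excluded with
an enumerated record. A metric with no scoreable material is `NA`.

## The inference protocol

The analysis table is long format — one row per participant × item ×
condition — and each metric is modelled with a linear mixed model:

$$y = \beta_0 + \beta_G G + \beta_C C + \beta_{GC} GC +
      \beta_P \mathrm{PPVT} + \beta_A \mathrm{Age} + Zb + \varepsilon$$

with Group and Condition effect-coded ±1. The orientation — autism $+1$,
non-autism $-1$; music $+1$, speech $-1$ — is a documented convention;
with two levels flipping it only flips coefficient signs.
Receptive vocabulary (PPVT-R) and age are centered at the mean over
*unique participants*, not over rows, so unequal trial counts cannot bias
the centers. Participants and items are crossed random factors; the
maximal structure the design licenses is by-participant intercepts and
condition slopes and by-item intercepts, condition and group slopes (the
by-item group slope has a config switch, since opinions differ on whether
a between-participant factor earns an item slope). Random slopes use the
numeric ±1 codes so that correlated and uncorrelated parameterizations
nest cleanly. Fixed-effect tests use Satterthwaite degrees of freedom via
`lmerTest`.

**Random-structure reduction.** When the maximal model fails — a
convergence warning or a singular fit (variance within `1e-4` of the
boundary), which in practice is the common failure — the reduction is
deterministic: (1) remove the random correlations; (2) repeatedly remove
the component with the smallest estimated variance, slopes before
intercepts and item-side before participant-side on ties (items are the
better-replicated factor), refitting after each removal until a model
converges. The full trail of attempts is kept in the result and is
reproducible from the data alone. If no structure converges the fit
errors, carrying the trail.

**Contrasts.** Simple effects — group within condition and condition
within group — are estimated on the fixed-effect scale with `emmeans`
(covariates at their centered means, Satterthwaite df) and
Holm–Bonferroni-corrected within the per-model family of four contrasts.
The family is per model, not global across metrics — the `emmeans`
convention, and the natural unit of the error-rate guarantee here.
Group characteristics tables are compared with Welch's *t* (unequal
variances, Welch–Satterthwaite df) computed from summary statistics, with
pooled-SD Cohen's *d* using $(n-1)$ weights — the variant that reproduces
the published values where any variant does.

## What the synthetic studies emulate

No recordings are distributable, so the package carries a generator that
reproduces the study *design* end to end and is itself first-class, tested
code. The design constants: 33 autistic and 30 non-autistic participants;
10 sentences of 2–6 syllables (counts 2,2,3,3,4,4,5,5,6,6, the actual
item-length distribution), each produced with an early or a late focus in
both a speech and a song version — 40 model utterances; a female model
voice with a male variant exactly 1200 cents lower (male participants of
12 and over hear the male voice); the focused word raised in pitch
(default +200 cents) and lengthened (default ×1.3), the documented
acoustics of focus in Mandarin; song versions quantized to the
equal-tempered semitone grid of the register tonic with near-isochronous
note durations (mean 0.5 s vs 0.22 s speech rhymes).

Imitations are the model with noise: per-syllable pitch error Gaussian on
the cents scale (multiplicative in Hz), duration error a Gaussian
multiplicative ratio, onsets rebuilt by accumulating imitated durations
plus jittered gaps, whole-octave displacements injected per syllable
(default rate 0.04, echoing the reported ~4% adjustment rate; 80% of them
downward, as creak lowers F0), and missing F0 injected at 0.01. Each
participant carries two lognormal ability factors (pitch, duration;
$\tau = 0.25$ and $0.30$) scaling their noise SDs, which is what gives the
trial table realistic between-participant variance for the mixed models to
absorb.

The group × condition noise SDs default to values back-solved from the
published condition means via two closed forms: for pitch noise
$\varepsilon \sim N(0, \sigma)$ the expected absolute deviation is the
folded-normal mean $\sigma\sqrt{2/\pi}$, and for a duration-ratio SD $s$
the per-syllable time-error probability is $2\Phi(-0.25/s)$. These are
realism defaults, not claims: in particular a single $\sigma$ per cell
cannot simultaneously reproduce the published absolute-pitch means (groups
nearly equal in speech) and relative-pitch means (autism group ~19% worse
in speech), because the two metrics share one noise source in this
generator while real speakers can err in register and in interval
independently. The defaults follow the relative-pitch pattern.
`directional_pattern_config()` is the related validation configuration
used for the qualitative acceptance check — the same directional pattern
(autism noisier on pitch in speech only, noisier on duration in song
only, both groups more precise on pitch in song) at effect sizes chosen
for high power at the default study size, so that the sign/significance
pattern check does not hinge on a marginal effect.

What the generator does **not** emulate: audio (no formant or voice-quality
synthesis), Mandarin tone categories, serial-position or learning effects,
and any non-Gaussian error structure. Passing calibration tests therefore
show that the *pipeline* is correct and the *inference layer* calibrated —
not that real imitation errors are Gaussian.

```{r truth}
cfg <- sim_config(seed = 1)
simulation_truth(cfg)$expected
```

## Numerical choices and degenerate inputs

* Folding target $(-600, 600]$: the interval must be half-open for
  idempotence; the boundary case +600 ("not more than half an octave") is
  untouched, and −600 folds to +600, preserving magnitude.
* Time-error threshold strict (> 25%), contour/interval thresholds
  inclusive (≥ 50, ≥ 100 cents), following each rule's wording.
* A pitch sample exactly on a rhyme boundary belongs to the later rhyme.
* Durations are floored at 5% of the model duration during generation, so
  the additive duration-noise model cannot produce non-positive rhymes;
  the closed-form calibration therefore holds when
  $s \times \text{ability} \lesssim 0.5$ (floor probability < 3%), and the
  analytic-recovery check uses SDs in that regime.
* Convergence treats singular fits as failures; `bobyqa` is the optimizer
  throughout, and fits are deterministic given the data.
* Empty contrast families, single-element Holm input, and all-`NA` metric
  columns degrade to `NA`/identity rather than erroring.

## Problem sizes used in the checks

The test suite calibrates the type-I error of the Group test on 200
simulated studies of 12+12 participants × 20 trials (a size at which the
whole calibration runs in a few minutes), recovery of an injected
duration interaction at the same size, metric/oracle equivalence on 1000
randomized pairs, and the closed-form calibrations on 600 trials (3000
syllables). The qualitative pattern check runs one full-size study
(63 participants, 2520 trials). `scripts/acceptance.R` recomputes the
same quantities from scratch at the same sizes.

## Known limitations

* Syllable alignment is by index; no dynamic realignment of insertions or
  deletions (excluded trials are reported instead).
* The Satterthwaite/`emmeans` path requires `lmerTest`; there is no
  Kenward–Roger option.
* The Welch/Cohen's-d reproduction of published summary tables is limited
  by the 2-decimal rounding of the printed means and SDs; *d* values where
  formula variants disagree at that precision are not asserted.
* The generator's single noise source per cell couples absolute and
  relative pitch accuracy (see above); studies of dissociations between
  the two need an extended error model.
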