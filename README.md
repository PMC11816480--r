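# vocalmatch

Scores how accurately a person imitates the **pitch** and **timing** of a
model utterance — a spoken sentence or its sung counterpart — and runs the
mixed-model inference protocol used in group comparisons of vocal
imitation (e.g. autistic vs non-autistic children in two-group,
two-condition imitation designs). It is written for researchers in
clinical bioacoustics and vocal phenotyping who have syllable-aligned
prosody annotations (Praat TextGrid + pitch track, ProsodyPro-style, or a
flat per-syllable CSV) and want the full path from annotation files to
fitted models without touching audio.

## What it computes

Each trial pairs a model utterance with its imitation, syllable by
syllable (one record per syllable rhyme: onset, duration, median F0). All
pitch comparison is in cents, $1200\log_2(f_i/f_m)$, and octave errors —
imitated pitches displaced by ~12 semitones, typically via creaky voice —
are folded into $(-600, 600]$ cents before any metric (a 700-cent
deviation becomes $12-7=5$ semitones in magnitude). Seven per-trial
metrics result:

| metric | definition |
|---|---|
| absolute pitch deviation (cents) | mean over syllables of the folded absolute deviation |
| relative pitch deviation (cents) | mean of $\|\,\|I_i\| - \|I_m\|\,\|$ over consecutive-syllable pitch intervals |
| pitch contour errors (count) | up/down/level mismatches at a ±50-cent direction threshold |
| pitch interval errors (count) | interval magnitudes differing by ≥ 100 cents |
| absolute duration difference (ms) | mean absolute rhyme-duration difference |
| relative duration difference (ms) | mean absolute interonset-interval difference |
| time errors (count) | syllables deviating > 25% of the model duration |

The stats layer provides Welch's *t* and pooled-SD Cohen's *d* from
summary statistics, effect-coded (±1) linear mixed models with crossed
participant/item random effects, Satterthwaite tests, a deterministic
random-structure reduction (drop correlations first, then the
smallest-variance component, slopes before intercepts, until
convergence), `emmeans` simple-effect contrasts with Holm–Bonferroni
correction, and Pearson correlations. A synthetic-study generator
reproduces the full design — 33 + 30 participants, 10 sentences of 2–6
syllables × early/late focus × speech/song, a male model voice one octave
below the female — with controllable noise, so everything is testable
without recordings.

## Worked example

Score one three-syllable trial, then simulate and analyse a full study:

```r
library(vocalmatch)

model <- utterance("s03_early", "model", "speech", "early", "model_female",
  syllable_events(onset_s = c(0.10, 0.40, 0.80),
                  duration_s = c(0.20, 0.30, 0.25),
                  median_f0_hz = c(200, 250, 220)))
imit <- utterance("s03_early", "imitation", "speech", "early", "p01",
  syllable_events(onset_s = c(0.12, 0.45, 0.85),
                  duration_s = c(0.25, 0.28, 0.40),
                  median_f0_hz = c(210, 240, 450)))
score_pair(utterance_pair(model, imit))
#>   abs_pitch_dev_cents rel_pitch_dev_cents contour_errors interval_errors
#> 1                64.7                132.              0               2
#>   abs_dur_diff_ms rel_dur_diff_ms time_errors n_syllables n_scoreable_syllables
#> 1            73.3              15           1           3                     3
```

The 450 Hz third syllable is an octave error against the 220 Hz model
(flagged and folded to a 38.9-cent deviation, hence the modest 64.7-cent
mean); its duration (400 vs 250 ms, +60%) is the one time error; the
imitation's first rhyme is exactly 25% long — *not* an error, the
threshold is strict.

```r
study <- simulate_study(sim_config(seed = 1))
study
#> <vm_study> 63 participants, 80 model utterances, 2520 scored trials (0 excluded)

fit <- fit_lme(study$trials, "abs_dur_diff_ms")
fit
#> Linear mixed model for abs_dur_diff_ms (n = 2520 trials)
#> Random structure: subject_intercept, subject_condition_slope, item_intercept,
#>   item_condition_slope, item_group_slope (uncorrelated)
#>             effect estimate    se   df      t        p
#>          Intercept  106.000 4.830 63.4 22.000 2.52e-31
#>              Group   20.100 5.680 60.7  3.540 7.68e-04
#>          Condition   15.400 1.810 42.9  8.480 1.02e-10
#>             PPVT-R    0.125 0.246 59.0  0.507 6.14e-01
#>                Age    4.250 2.000 59.0  2.120 3.80e-02
#>  Group x Condition   10.400 1.580 61.0  6.590 1.17e-08

marginal_means_contrasts(fit)
#>              contrast     within estimate    se   df     t    p_raw   p_holm
#> 1 autism - non_autism      music    61.12 11.80 70.1  5.18 2.03e-06 6.08e-06
#> 2 autism - non_autism     speech    19.40 11.80 70.1  1.64 1.05e-01 1.05e-01
#> 3      music - speech     autism    51.58  4.71 59.0 10.95 7.61e-16 3.04e-15
#> 4      music - speech non_autism     9.85  4.91 60.5  2.01 4.92e-02 9.84e-02
```

With the default noise configuration (autism group noisier on duration in
the song condition), the fitted Group coefficient (+1 = autism) and the
Group × Condition interaction (+1 = music) are both positive and the Holm-
corrected contrasts localize the group difference to the music condition —
the qualitative pattern the generator injects.

A command-line wrapper covers the same stages
(`inst/cli/vocalmatch simulate|score|analyze|table1`), and
`sim_config_from_yaml()` reads flat YAML configs.

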