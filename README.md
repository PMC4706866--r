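# comfortEEG

Single-trial EEG classification of stereoscopic visual comfort.

Stereoscopic ("3D") displays force the eyes to converge on an apparent
depth while focusing on the physical screen. When this
vergence-accommodation conflict is strong, viewing becomes uncomfortable.
`comfortEEG` implements a passive brain-computer interface that detects,
from about one second of EEG following an object's appearance, whether the
viewer saw a comfortable ("C") or an uncomfortable ("NC") stereoscopic
depth — the kind of signal an adaptive display could use to tune its
stereo effect on the fly.

The pipeline is the one used in single-trial ERP classification research:

* **Spatial filtering** — regularized eigen Fisher spatial filters (REFSF)
  solve the generalized eigenproblem `S_b w = λ S_w w` between the
  between-class scatter of class-mean ERPs and the shrinkage-regularized
  within-class residual scatter, projecting 28 channels onto 5
  discriminant "virtual channels". For spectral features, common
  spatio-spectral patterns (CSSP: CSP on a delay-embedded channel set)
  extract log band-power in delta/theta/alpha/beta bands.
* **Features** — a 1 s ERP window starting 100 ms post-marker, decimated
  by 16 (5 × 32 = 160 features); optionally fused with 24 CSSP features
  (z-scored, reduced 184 → 50 by a class-median-ratio filter).
* **Classifier** — shrinkage LDA: `w = Σ̃⁻¹(μ_C − μ_NC)` with
  `Σ̃ = (1−λ)Σ + λ·tr(Σ)/d·I` and an analytic Ledoit-Wolf λ.
* **Aggregation** — Monte-Carlo majority voting over clusters of n
  same-condition trials, with its binomial oracle
  `Σ_{k>n/2} C(n,k) pᵏ(1−p)ⁿ⁻ᵏ`, exact binomial chance bounds, and cohort
  summaries.

Because the underlying human EEG was never deposited, the package includes
a first-class synthetic cohort generator (`generate_session()`,
`generate_cohort()`) that reproduces the study's signal structure: 28
channels at 512 Hz, 160 trials per condition spaced ~5.5 s apart, a 1/f
background, a condition-dependent ERP peak, post-stimulus alpha
suppression and theta enhancement in NC, optional blink artifacts, and
log-normal inter-subject effect spread.

## Worked example

```r
library(comfortEEG)

cfg <- make_default_config()          # 12 subjects, 160 trials/condition
s   <- generate_session(cfg, "S01", seed = 101)
s
#> <raw_session> subject S01: 28 channels x 1354166 samples @ 512 Hz (2644.9 s)
#>   events: C=160, FLAT=160, NC=160

res <- run_subject(s, pipeline_config())   # offline ERP pipeline
res
#> <subject_result> S01: 62.50% single-trial accuracy (160 train / 160 test trials)

chance_threshold(res$n_test, alpha = 0.01)
#> [1] 60

vote <- majority_vote_mc(res$correct, res$test_labels, n = 3,
                         n_draws = 1e5, seed = 1)
vote
#> <majority_vote_estimate> n = 3: 68.44% (SE 0.103, 100000 draws)
100 * binomial_majority(mean(res$correct), 3)   # independence oracle
#> [1] 68.35938
```

The single-trial accuracy (62.5% here) is one synthetic subject's score on
the held-out second half of its trials; 60% is the exact binomial bound
for beating chance at α = 0.01 with 160 test trials; and the majority-vote
estimate shows how accuracy grows when three presentations of the same
condition are pooled, agreeing with the closed-form binomial oracle.
Cohort-level runs (`run_cohort()`), channel-importance ranking
(`channel_importance()`), the reduced 14-channel montage
(`select_channels()`), the simulated online mode
(`pipeline_config(mode = "online")`), and ERP/CSSP feature fusion
(`feature_set = "ERP+CSSP"`) follow the same pattern; see the vignette in
`vignettes/comfortEEG-methods.Rmd` for the full model description.

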