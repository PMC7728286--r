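# collinobs

Observer models for collinearity judgment under sensory uncertainty.

## The scientific problem

In a simple form of contour integration, an observer judges whether two
horizontal line segments separated by a vertical occluder belong to the same
line. Stimuli appear at one of four retinal eccentricities
(y = 0, 4.8, 9.6, 16.8 dva), which manipulates sensory noise σ<sub>x</sub>(y)
trial by trial. On collinear trials the two vertical positions are equal and
drawn from N(y, σ<sub>y</sub>²) with σ<sub>y</sub> = 0.48 dva; on
non-collinear trials they are independent draws. The scientific question is
*how* observers use their sensory uncertainty when deciding: optimally
(Bayes), not at all (a fixed criterion), or via a heuristic that scales a
criterion linearly with the noise (Lin).

With measurements x<sub>L</sub>, x<sub>R</sub>, u = x<sub>L</sub> −
x<sub>R</sub> and v = (x<sub>L</sub> + x<sub>R</sub>)/2, the Bayes
observer's log posterior ratio is the quadratic

d\*(u, v) = K − A·u² + c<sub>v</sub>·(v − y)²,  A > 0, c<sub>v</sub> > 0,

so it reports "collinear" when |u| ≤ b(v) with b(v)² = (K +
c<sub>v</sub>(v−y)²)/A — a boundary that widens with noise and depends on
both measurements. The package implements this observer, the Fixed and Lin
alternatives, and suboptimal Bayesian variants (noise mismatch, width
mismatch, decision noise, a hybrid, a nonparametric per-level criterion, a
trial-history extension, and the Vernier/height-judgment rule used to
estimate noise independently) — ten models in all — plus the full analysis
pipeline: exact response probabilities, slice-sampling MCMC, PSIS-LOO model
comparison, hierarchical random-effects model selection with protected
exceedance probabilities, psychometric binning, efficiency relative to the
Bayes-optimal observer, and parameter/model recovery harnesses.

## Worked example

Simulate a heuristic (Lin) observer on one experiment's worth of trials,
fit two competing models, and compare them:

```r
library(collinobs)

design <- make_default_design()
truth <- observer_params("lin", sigma_x = c(0.35, 0.55, 1, 2),
                         levels = c(0, 4.8, 9.6, 16.8),
                         lapse = 0.03, kappa0 = 0.15, kappa1 = 1.3)
trials <- generate_collinearity_trials(design, 2400, seed = 1)
trials <- simulate_responses(truth, trials, seed = 2)

fit_lin <- sample_posterior("lin", trials, n_chains = 2, n_samples = 150,
                            burn_in = 50, seed = 3)
fit_fix <- sample_posterior("fixed", trials, n_chains = 2, n_samples = 150,
                            burn_in = 50, seed = 4)
psis_loo(fit_lin)
psis_loo(fit_fix)
round(fit_lin$rhat, 3)
```

Output from this exact script:

```
PSIS-LOO: -1486.01 (SE 18.10) over 2400 trials, 300 draws; k > 0.7 on 0 trial(s)
PSIS-LOO: -1511.73 (SE 17.32) over 2400 trials, 300 draws; k > 0.7 on 0 trial(s)
   sigma_0  sigma_4.8  sigma_9.6 sigma_16.8     lambda     kappa0     kappa1
     1.055      1.012      1.005      1.001      1.039      1.009      1.018
```

The generating Lin model beats the uncertainty-blind Fixed model by about
26 LOO points (higher is better) on one synthetic subject — the same kind
of evidence the pipeline aggregates across subjects to distinguish
probabilistic from non-probabilistic observers — and all Gelman–Rubin
statistics sit near 1. `group_bms()` aggregates such per-subject
scores into expected model frequencies and protected exceedance
probabilities; `efficiency()` quantifies accuracy relative to a simulated
Bayes-optimal observer with the same noise.

A command-line interface covers the same pipeline:
`simulate`, `fit`, `compare`, `analyze`, `recover` (see `?cj_run`), e.g.

```sh
Rscript -e 'collinobs::run_cli()' simulate --task collinearity --n 2400 --seed 1 --out trials.tsv
```

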