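# promsig — spatial promoter recognition signatures

Transcription factors in yeast bind short, degenerate sites, and a
single site rarely carries enough information to single out a target
promoter: the same 6–10 bp sequence occurs by chance all over the
genome, and bound loci often show no expression change when the factor
is deleted.  `promsig` models the additional, promoter-level information
a factor can exploit — where its sites sit relative to the transcription
start site (TSS), which strand they prefer, and how many there are — as
a generative *promoter recognition signature*, and quantifies how much
discriminatory information that signature adds.

The package is for computational biologists who want to train such
models on promoter sets (e.g. ChIP-derived target sets), test whether
the spatial structure is real, measure its information content, and use
it to rank candidate targets.

## The model

Each promoter (5'→3', TSS at the right end, ≤ 1,003 bp) is generated by
a promoter-level hidden Markov model.  A regulation indicator
R ~ Bernoulli(ρ) decides whether the promoter carries the signature.  If
it does, binding sites (emitted from the factor's frequency matrix, on
either strand) start at position *p* bp upstream of the TSS with
probability

    q(p, strand) = λ · σ(η(p − (μ − ω))) · σ(η((μ + ω) − p)) · {τ or 1 − τ}

— an approximately flat plateau of height λ between μ − ω and μ + ω with
logistic edges of slope η (fixed at 0.1), split between strands by τ.
Everything else is GC-weighted background (GC = 0.38).  A consistency
constraint forces an R = 1 promoter to contain at least one complete
site.  The five trained parameters are ρ, μ, ω, τ, λ; a *monosite*
variant (exactly one site, position drawn from the normalized plateau)
covers factors that rely on a single site, and an information criterion
chooses between the variants.

Around this core the package provides exact inference
(`forward_backward`, verified against a path-enumeration oracle to
1e-9), EM training with analytic ρ/τ updates and simulated annealing of
(λ, μ, ω) from multiple starts (`em_fit`), strand and spacing
likelihood-ratio controls including a segment-swap scrambler that
preserves composition and site strength while destroying position
(`lrt_strand`, `scramble_set`, `spacing_control_test`), an
unbound-region screen (`unbound_screen`), sampling-based
Kullback-Leibler specificity with an exact small-model oracle
(`sampled_kl`, `exact_kl`, `single_site_baseline`), four target rankers
with resampling-based evaluation (`rank_by_signature`,
`rank_by_thermodynamic`, `rank_by_top_site`, `rank_by_chip`,
`evaluate_topk`, `bootstrap_method_comparison`, `binomial_wins_test`),
and a synthetic benchmark generator (`generate_training_set`,
`generate_benchmark`) so every stage is testable without external data.

## Worked example

Train a signature on 200 synthetic promoters whose generating truth is
ρ = 0.6, μ = 250, ω = 120, τ = 0.8, λ = 0.008:

```r
library(promsig)

pm <- matrix(0.2 / 3, nrow = 8, ncol = 4)
cons <- c(1, 3, 2, 4, 1, 2, 3, 4)
for (i in 1:8) pm[i, cons[i]] <- 0.8
motif <- freq_matrix(pm, name = "toyTF")
bg <- background_model(gc = 0.38)

truth <- signature_model(motif, bg,
                         spatial_params(rho = 0.6, mu = 250, omega = 120,
                                        tau = 0.8, lambda = 0.008),
                         variant = "multisite", length = 1003)
train <- generate_training_set(truth, n = 200, seed = 11)

fit <- em_fit(train$seqs, motif, bg, n_starts = 3,
              schedule = anneal_schedule(t_init = 1, n_temps = 5, steps = 10),
              seed = 5, max_iter = 30)
fit
#> <promsig_fit> multisite, loglik -272138.254 after 23 iterations (start 3, converged)
#> <spatial_params> rho=0.5708 mu=248.6 omega=124.2 tau=0.8119 lambda=0.01083 eta=0.10
```

The fit recovers the plateau (μ̂ = 249 vs 250, ω̂ = 124 vs 120), the
strand bias (τ̂ = 0.81 vs 0.80) and the signature-carrying fraction
(ρ̂ = 0.57; the estimate sits slightly below 0.6 because
signature-carrying training promoters are conditioned on containing a
site — see the vignette).  The strand preference is highly significant:

```r
lrt_strand(train$seqs, fit, seed = 6,
           schedule = anneal_schedule(t_init = 1, n_temps = 3, steps = 6),
           max_iter = 12)
#> <model_comparison> strand bias (tau = 0.5 null): LRT stat 53.657 (df=1), p = 2.388e-13
```

Per-promoter inference gives the posterior that a promoter carries the
signature (the signature ranking score) and where its sites sit:

```r
forward_backward(fit$model, train$seqs[[1]])
#> <lattice_posteriors> loglik=-1362.4794 E[R]=0.6499 expected sites=1.3797
```

And the exact binomial sign test used to aggregate per-factor wins of
one ranking method over another:

```r
binomial_wins_test(12, 15)
#> [1] 0.01757812
```

A command-line front end over the same functions (subcommands
`simulate`, `fit`, `screen`, `scramble-test`, `info`, `rank`,
`evaluate`) ships at `inst/cli/promsig.R`.

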