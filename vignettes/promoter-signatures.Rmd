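---
title: "Modelling spatial promoter recognition signatures"
author: "promsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial promoter recognition signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promsig)
```

## The problem

A yeast transcription factor recognizes short (6–10 bp), degenerate
sites, and an individual site rarely carries enough information to mark a
specific target promoter: identical sequences occur by chance throughout
the genome, and bound loci frequently show no expression change when the
factor is deleted.  One resolution is that a factor's true targets carry
a joint, promoter-level pattern — a characteristic *position* of sites
relative to the transcription start site (TSS), a *strand* preference,
and a characteristic *number* of sites — which this package calls a
promoter recognition signature and models generatively.

## The model

Promoters are stored 5'→3' with the TSS at the right end; "position"
always means distance in bp upstream of the TSS, and a site's position is
the distance of its TSS-proximal end.  For one factor with frequency
matrix $f$ (width $w$) and an iid GC-weighted background $b$
(GC $= 0.38$ by default), each promoter of length $L$ is generated as
follows.

A binary regulation indicator $R \sim \mathrm{Bernoulli}(\rho)$ decides
whether the promoter carries the signature.  If $R = 0$ the whole
sequence is background.  If $R = 1$, a hidden site-state chain runs along
the promoter: from a background state, a site may start at position $p$
with probability

$$q(p, s) \;=\; \lambda\,
   \sigma\!\big(\eta\,(p - (\mu - \omega))\big)\,
   \sigma\!\big(\eta\,((\mu + \omega) - p)\big) \times
   \begin{cases} \tau & s = \text{forward} \\ 1 - \tau & s = \text{reverse,} \end{cases}$$

where $\sigma$ is the logistic function.  This traces an approximately
flat plateau of height $\lambda$ between $\mu - \omega$ and
$\mu + \omega$ whose edges rise with slope $\eta$ (fixed at $0.1$; a
soft edge makes the likelihood surface much friendlier to optimize than
a hard window).  A started site emits $w$ bases from $f$ (or its reverse
complement), sites never overlap, and must fit inside the sequence.  A
consistency constraint ties $R$ to the outcome: an $R = 1$ promoter must
contain at least one complete site.  The five trained parameters are
$\rho, \mu, \omega, \tau, \lambda$.

Two remarks on this formulation.  First, the plateau's
logistic-product form is one natural closed form with the properties a
site-enrichment plateau needs — height $\lambda$, center $\mu$,
half-width $\omega$, edge slope $\eta$ — and the package applies it to
a site's TSS-proximal end (applying it to the start or center instead
would shift everything by at most $w$ bp).

Second, the **monosite** variant (for factors that rely on strictly one
site) places exactly one site at a position and strand drawn from the
*normalized* plateau distribution $q / \sum q$.  In a literal one-site
lattice with per-position initiation, $\lambda$ only rescales the
single-site emission mass and is absorbed almost perfectly by $\rho$ —
the pair is practically unidentifiable, and fits of monosite data
collapsed ($\hat\rho \to 0$) in our experiments.  Normalizing removes
$\lambda$ exactly, so the monosite variant has four genuine parameters
($\rho, \tau, \mu, \omega$), which is also the parameter count its BIC
comparison uses.

### Inference

`forward_backward()` collapses the per-position state lattice into two
running odds-against-background masses (no site yet / at least one site)
and sums site blocks as precomputed emission-odds factors, giving exact
$O(Lw)$ likelihood evaluation after an $O(Lw)$ per-dataset
precomputation; running odds are rescaled in counted steps of $10^{300}$
so strongly matching promoters cannot overflow.  The reported joint
log-likelihood $\log P(N, C{=}1)$ is exact: the test suite checks it
against an independent path-enumeration oracle at $10^{-9}$ relative
tolerance on hundreds of random instances.

The package distinguishes two likelihoods:

* `loglik` — the joint $\log P(N, C{=}1)$, the quantity EM maximizes
  (with $C$ treated as an observed variable);
* `loglik_cond` — the log density of the model's *normalized* sequence
  distribution, the mixture
  $\rho\,P(N \mid R{=}1, C{=}1) + (1-\rho)\,P_b(N)$, which is exactly
  what `sample_promoter()` draws from ($R$ is drawn once; the walk of an
  $R{=}1$ promoter is resampled until it contains a site).  This density
  sums to 1 over all sequences — an identity the tests verify by brute
  enumeration — and is the one used for information calculations.

`E[R]`, the posterior probability that a promoter carries the signature,
is the signature ranking score (computed with the prior replaced by
$\rho = 0.5$; the prior is a monotone transform and never changes the
order).

### Fitting

`em_fit()` runs EM from multiple random starts (default 15): exact
posteriors (E-step), analytic updates $\hat\rho = \overline{E[R]}$ and
$\hat\tau$ = forward share of posterior site-start mass (both are exact
M-steps: $\tau$ cancels from the stay probability, so it appears only in
the strand split), and a simulated-annealing update of
$(\lambda, \mu, \omega)$ on the marginal log-likelihood with Metropolis
acceptance.  The annealer always includes the incumbent among visited
points and returns the best visited, so each full EM iteration is
non-decreasing (asserted at $10^{-6}$ tolerance).  Starts draw $\mu$
uniformly over $[0, L]$, $\omega$ over $[25, L/2]$, $\lambda$ over
$[1/L, 20/L]$, with $\rho = \tau = 0.5$.  The production schedule cools
geometrically by $0.9$ over 10 temperature levels with 50 proposals
each; the 15-start default and the annealing of the spatial triple are
the production configuration, while the schedule's depth is configurable
and reduced in the test suite (sizes below).

One bias is worth knowing about: because training promoters that carry
the signature are, by construction, conditioned on containing at least
one site, the joint-likelihood EM slightly over-estimates $\lambda$ and
under-estimates $\rho$ (it prefers parameter values that make the
consistency event likelier).  At the simulation conditions used here the
median $\hat\rho$ bias is $\approx 0.05$–$0.08$, within the recovery
tolerances asserted by the tests.

### Controls

* **Strand** — likelihood-ratio test against a nested refit with
  $\tau = 0.5$ (df 1).  The null is warm-started from the full fit, so
  under-optimization can only make the test conservative.
* **Spacing** — `scramble_set()` duplicates the set (to 600 sequences by
  default), then repeatedly swaps equal-length random segments (5–75 bp)
  whose borders are not crossed by any site scoring $\ge 0$ (log2, either
  strand, rescanned against current content).  This conserves lengths,
  per-set base counts, and the strength and number of existing sites
  while destroying their positions.  Refitting the original data with
  $(\mu, \omega)$ pinned to scramble-trained values gives a df-2 LRT that
  separates genuine spatial restriction from what promoter lengths alone
  explain; a uniform-plateau null (`lrt_spacing_uniform()`) provides the
  initial significance test.  Note that the border rule prevents site
  destruction but not creation at swap junctions, so over very long runs
  new scoring windows accumulate and an increasing fraction of
  iterations is skipped (skips are counted and reported); positional
  structure is destroyed long before this saturation matters.
* **Density** — multisite vs monosite is a structural change, so the
  variants are compared by BIC with 5 vs 4 parameters; the expected
  number of sites per promoter under the chosen fit is reported.
* **Unbound screen** — `unbound_screen()` fits 20 random sets of
  promoters unbound in every condition, 20 starts each; a signature is
  discarded if the median per-set maximum $\hat\rho$ exceeds 0.15 or any
  $\hat\rho$ exceeds the signature's own, marking matrices that "fit"
  plain background.

### Information

The specificity of a signature is the Kullback–Leibler divergence
between the model's normalized sequence distribution and the background
over the same length, in nats (`bits = TRUE` converts).  It is estimated
by sampling ($N = 10{,}000$ by default, with the Monte-Carlo standard
error), and validated against exact enumeration for models up to 10 bp.
`single_site_baseline()` builds the spacing-agnostic comparison model —
one site, no strand bias, uniform position — whose KL isolates the
binding-site information at promoter scale; the difference to the full
model's KL is the spatial information contributed by position, strand
and density.

### Target ranking and evaluation

Four rankers score promoters: the signature posterior `E[R]`
(override $\rho = 0.5$); the best single site; a thermodynamic model in
which one protein molecule is competed for by every possible site, a
site's affinity is $e^{\text{score}}$ (natural-log odds) and a
promoter's score is its share of the total affinity (shares sum to 1);
and ChIP p-values (smallest across conditions).  `evaluate_topk()`
compares the mean deletion expression change of a ranker's top
$K = 50$ against a null interval from 5,000 resampled sets of $K$ ORFs;
`bootstrap_method_comparison()` resamples promoter–expression *pairs*
jointly 10,000 times and counts how often one method's top-$K$ magnitude
beats the other's; `binomial_wins_test()` aggregates per-factor wins by
an exact Binomial$(n, 1/2)$ upper tail.  The magnitude compared is
$|\mathrm{mean}(\Delta)|$ — the absolute value of the signed mean, not
the mean absolute change.

## What the synthetic generator emulates — and what it does not

`generate_training_set()` and `generate_benchmark()` produce promoters
sampled from a signature model at variable lengths (≤ 1,003 bp), with
ground-truth site annotations, surrogate ChIP p-values (Beta(0.5, 10)
for regulated promoters, uniform otherwise) and per-ORF deletion
expression changes `effect * regulated + N(0, noise_sd)`.
`prepare_promoter()` applies the real-data length policy: trim to
1,003 bp from the 5' end, pad short sequences with 38% GC fill flagged
as masked (lowercase in memory, BED sidecar on disk) within which no
site may start.

The generator's background is iid; real promoters have nucleosome
structure, local composition biases, repeats, and neighboring-gene
effects, and real binding data carry condition-dependence and technical
noise that a Beta/uniform surrogate only sketches.  Passing tests on
this synthetic material therefore demonstrates correctness of the
algorithms and calibration of the statistics under the model's own
assumptions — not that any particular biological factor has a signature.

## Numerical choices and problem sizes

Defaults: pseudocount $10^{-4}$ on probability matrices (keeps log-odds
finite without distorting well-specified motifs); ambiguous bases score
as background (log-ratio 0) and exclude site initiation; EM tolerance
$10^{-4}$ nats, at most 200 iterations; ties in rankings broken by
promoter id so every run is reproducible; all randomness flows through
R's RNG and a single seed.

The test suite and `scripts/acceptance.R` use deliberately moderate
sizes, chosen as the smallest at which each property is comfortably
measurable: 200 random oracle instances (lengths to 30 bp, motifs to
5 bp); full enumeration of $4^6$–$4^7$ sequences for normalization;
$N = 10{,}000$ KL samples against $4^{10}$ enumeration; 20 replicates of
a 200-promoter, 1,003-bp recovery study at
$\rho=.6, \mu=250, \omega=120, \tau=.8, \lambda=.008$ (2 EM starts, a
5×10 annealing schedule, 25 iterations); 100-replicate LRT calibrations
on 80 promoters of 300 bp with an 8-bp, 0.85-consensus matrix
($\tau=.95$ for strand power; $\mu=120, \omega=40$ on 150–300 bp
promoters for spacing power; scrambles of 160 sequences at $2\times10^4$
iterations); and a 500-promoter benchmark (effect $-2$, noise 1,
$\rho=.1$) whose training set is the promoters with a surrogate binding
p-value below .05.  Production defaults (15 starts, $10^6$ scramble
iterations with the full $10^8$ production value a flag away, 5,000/10,000
resamples) remain available on every function.

## Known limitations

Position-independent emissions within sites; a single iid background
(no dinucleotide or nucleosome structure); one signature per factor (no
condition-specific mixtures); no inter-site spacing constraints between
specific site pairs; the unbound screen and LRTs are per-factor, with no
multiple-testing correction across factors.  The KL-to-target-count
arithmetic (how many nats would "suffice" for a given number of
targets) depends on genome-size assumptions and is deliberately not
computed by this package.
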