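---
title: "Models and methods behind phylosyndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylosyndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosyndrome)
```

## The scientific problem

Hypodermic (traumatic) insemination — sperm transfer through the partner's
epidermis via a needle-like stylet, bypassing the female genital opening —
has evolved repeatedly in the flatworm genus *Macrostomum*. Asking *how
often* it arose, whether it ever reverses, and which morphological changes
accompany it requires a chain of comparative methods: a reproducible rule
for scoring each species' mating syndrome from morphology, constrained
Markov models of discrete-character evolution, Bayesian stochastic mapping
of character histories, a conservative rule for counting independent
origins, tests of correlated evolution between trait pairs, and
phylogenetically corrected ordination and regression for the continuous
morphology. `phylosyndrome` implements that chain as reusable, tested
components, together with a synthetic-data generator that provides ground
truth for every stage.

## Syndrome classification

`classify_syndrome()` encodes an ordered decision list. Direct observation
of exclusively hypodermic received sperm is decisive. When sperm
observations are missing, the full hypodermic morphology (reduced or absent
sperm bristles, a simple antrum, a sharp stylet) is accepted instead,
because these traits show strong correlated evolution with the sperm
location (and that correlation is itself testable with the package's Pagel
machinery). Received sperm in the antrum indicates reciprocal copulation
when paired with a blunt stylet, or with retained bristles when the stylet
is sharp. Everything else is left `unclear` rather than guessed. The rule
id that fired is returned with each label, so every assignment is
auditable. A trinary "neutral" stylet counts as non-sharp wherever a rule
demands sharpness; this is the minimal reading of a rule set formulated in
terms of sharp versus blunt.

Binary codings for the Markov models put the hypodermic-like state at 0 and
the reciprocal-like state at 1 (or 2 in the trinary codings), so that a
"Dollo" model — no gains once the trait is lost — forbids transitions that
increase towards the reciprocal states out of state 0. Species with sperm
in both locations are grouped with the hypodermic state by default
(`both_as = "exclude"` drops them instead); missing values propagate as
missing and species are deleted listwise per analysis, never imputed.

## Quantitative trait handling

Body area is transformed as log10 of its square root (a linearised size);
all linear measures as log10. Species values are means of per-specimen
transformed values — log first, then average — because log-first
aggregation stabilises the variance of strongly right-skewed morphometrics;
the mean-then-log alternative is available (`log_first = FALSE`) and the
two orders are contrasted in the test suite. Per-trait specimen counts are
carried through to serve as regression weights.

## Constrained Mk models

Six rate-matrix templates are available via `build_template()`: `ER`,
`SYM`, `ARD`, and three loss-constrained variants — binary `Dollo` (only
1→0 free), trinary `ORD` (transitions forced through the intermediate
state), `ORD-Dollo` (ordered and no exit from 0), and trinary `Dollo`
(no gains out of 0 but the direct 2→0 loss allowed — deliberately
not an ordered model). Forbidden cells are structural zeros at every
parameter value, which the tests verify both on the matrices and on
simulated histories.

The likelihood (`mk_loglik()`) is Felsenstein's pruning algorithm with
per-branch transition matrices `expm(Qt)`; multifurcations are handled
natively, which is why polytomies are retained rather than arbitrarily
resolved (resolution would alter transition counts). The root is combined
under an equal prior by default — `stationary`, `observed`, or an explicit
vector are available — because reconstructions of this kind conventionally
use a flat root prior and the choice is exposed rather than hidden. Matrix
exponentials use an eigendecomposition fast path (one decomposition per Q,
reused across branches; exact closed form in the 2-state case) with
scaling-and-squaring as fallback for defective matrices.

Fitting (`fit_mk()`) maximises over log-rates with bounded quasi-Newton
iterations from multiple seeded starts (default 10; the pipeline uses 3,
which suffices for 1–6 parameter templates). Boundary maximum-likelihood
estimates (rates indistinguishable from zero) are reported as such.
AICc uses the standard small-sample correction `2k(k+1)/(n-k-1)` and is
undefined (returned as `NA`) when `n <= k + 1`. `compare_models()` flags
every model whose Akaike weight exceeds 0.15 for stochastic mapping, the
same inclusion rule used in the downstream pipeline.

## Stochastic character mapping

`sample_q_posterior()` samples the free rates by Metropolis-Hastings with
independent gamma(1, 1) priors — a prior that concentrates on low
transition rates — using multiplicative log-normal proposals auto-tuned
during burn-in to a 20–40% acceptance rate. Default chain sizes are
10,000 burn-in and 10,000 sampling iterations with thinning 10 (1000
retained draws); tests and the fast pipeline profile use 1000/1000/10.
Seeds are mandatory and chains are bit-reproducible.

`simulate_history()` draws a complete character history conditional on the
tip data and one rate matrix: pruning down-pass, joint node-state sampling
on the up-pass, then an exact conditional path on every branch by
uniformization (sampling the number of jumps of the uniformized chain given
the endpoints, then the jump states by forward-filtering against the
remaining-step kernel powers). Uniformization was chosen over rejection
sampling because it cannot stall on branches whose endpoint pair is
improbable under the drawn matrix; a single-branch analytic expectation and
a rejection-free invariant (simulated tip states always equal observations)
pin the implementation down in the tests.

`summarize_maps()` reports per-ordered-pair transition counts (mean and
empirical 2.5%/97.5% quantiles, kept integer-valued by type-1 quantiles)
and per-node state posteriors.

## The lower-bound origin rule

Counting "at least how many" independent origins of the derived state is
deliberately conservative: two derived patches count separately only if the
node path between them passes a node whose posterior probability of the
ancestral state exceeds the threshold (default 0.95). The implementation
marks every tip/node whose majority summarised state is derived, groups
them into connected patches, and merges patches whenever no high-confidence
ancestral node separates them; the separating node for every non-merged
pair is returned so each counted origin is auditable. The count is
provably non-increasing in the threshold, which the tests exercise.
Because the state at the root of a genus-level tree is often uncertain, the
result also reports the count excluding root-adjacent origins (groups whose
path to the root crosses no high-confidence ancestral node), so both
readings of root-adjacent events are available.

## Pagel's correlated-evolution test

Two binary traits are modelled as one 4-state chain over the joint states
00/01/10/11 with double transitions forbidden. The independent model has 4
free rates; the dependent model 8. Two exact identities anchor the
implementation: the independent-model likelihood factorises into the
product of the two single-trait likelihoods (with an equal joint root
prior), and the dependent model with paired rates equalised reproduces the
independent likelihood. Marginal likelihoods come from stepping-stone
sampling over a Beta(0.3, 1)-spaced power ladder (`beta_k = (k/K)^(1/0.3)`,
concentrating stones near the prior, where the integrand varies fastest);
support is summarised as `BF = 2 (logZ_dep - logZ_ind)`. Convergence of
the rate chains is assessed with the potential scale reduction factor
across independent chains, flagging any parameter above 1.1.

Chain sizes here are configuration, not science: production analyses of
this kind run hundreds of millions of iterations on clusters, and the
package defaults (and test sizes) are scaled down to what a laptop
verifies statistically — the estimator is the same, only Monte-Carlo error
differs. The exponential prior's mean defaults to the mean
maximum-likelihood rate, capped at 100 because on weakly informative data
the ML rates saturate (the likelihood plateaus for fast chains) and an
uncapped mean would make the prior improperly flat; a uniform prior on
[0, 100] is the alternative.
Reversible-jump hyperpriors are out of scope.

## Phylogenetic PCA and PGLS

`ppca()` estimates Pagel's lambda by maximising the multivariate GLS
likelihood, computes the evolutionary correlation matrix from
GLS-centred traits (the correlation matrix throughout, because the traits
mix scales and ordinal codes), and decomposes it. Ordinal categorical
traits enter as equally spaced integer codes — the minimal defensible
numeric embedding — and this is a documented choice, not a hidden one.
Scores standardise by the evolutionary standard deviations, so they are
invariant to trait rescaling; eigenvector signs are fixed so the dominant
trait of each component loads positively. On a star phylogeny the whole
construction collapses to ordinary correlation PCA, which is the
key degeneracy test.

`pgls_fit()` fits `y ~ X` by maximum likelihood under residual covariance
`sigma^2 W^(1/2) Corr W^(1/2)`, where `Corr` follows Brownian motion,
Pagel's lambda, an Ornstein–Uhlenbeck kernel `exp(-alpha d_ij)`, or the
identity, and `W = diag(1/n_i)` downweights species measured from few
specimens (variance proportional to `1/n`, the standard reading of
count weights; an SD-proportional variant is selectable). ML rather than
REML keeps AICc comparable across fixed-effect structures. The profile
likelihood of the structure parameter is retained on a grid so unimodality
and boundary estimates can be inspected. Predictive R² follows the
conditional-expectation construction: each species is predicted from all
others' residuals under the fitted covariance, and the statistic compares
prediction error against an intercept-only non-phylogenetic reduced model
(the headline variant) or an intercept-only phylogenetic one (isolating
the predictors' contribution after the phylogeny); both are computed and
labelled distinctly.

`coevolution_analysis()` ordinates the five stylet and four antrum traits
separately and regresses stylet PC1 on antrum PC1, with a rerun excluding
a species subset (typically the hypodermic-syndrome species, whose
uniformly simple genitalia could otherwise drive the association).

## The synthetic-data generator

The generator is the package's ground truth, emulating the shape of a
genus-wide survey: a pure-birth tree rescaled to unit depth (pure-birth
for guaranteed tip counts; a ~145-tip tree matches the study scale); a
received-sperm-location × bristle pair evolved under a *dependent* 4-state
process in which bristle loss runs roughly eightfold faster on a
hypodermic background, with all gains forbidden; an antrum state tracking
sperm location with a small decoupling probability; trinary refinements
that score recent losses (within the last 15% of tree depth) as
intermediate; 15 continuous traits with a planted one-factor correlation
(pairwise 0.6) whose factor is shifted in hypodermic species; specimen
counts from a shifted negative binomial with mean 8 (the study's
per-species sampling is of that order) and log-normal-style measurement
noise; and per-trait missing-completely-at-random gaps calibrated to the
study's coverage (about 30% of species unscored for sperm location, ~10%
for bristles, ~12% for the antrum).

What the generator does *not* emulate: structured missingness (real
missingness concentrates in rarely collected clades), behavioural traits,
and intraspecific correlation between measurement error across traits. A
passing test suite therefore demonstrates correctness of the methods under
these idealised conditions, not robustness to every pathology of field
data.

`simulate_planted_origins()` constructs the sharpest available test of the
origin-counting rule: nine disjoint clades are forced entirely into the
derived state, so the true number of origins is known by construction, and
the lower bound should land at or slightly below it.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use 100–150-tip trees with
25–100 replicates and fast MCMC profiles (1000/1000/10), sizes at which
each distributional claim is decided in seconds to a couple of minutes
while keeping Monte-Carlo error well inside the asserted margins.
Ultrametricity is accepted at a relative tolerance of 1e-6 of tree depth.
Likelihood scaling rescales partial likelihoods only when they fall below
1e-280, accumulating the log-scale correction per node. Ties in majority
states break toward the lower state index. Origin counting on a tree
where the derived state is absent returns zero rather than an error.

## Known limitations

* The Mk machinery covers 2–4 state chains (the study's state spaces);
  larger alphabets would work through the same code paths but are untested.
* Stepping-stone estimates at the default test ladder (30–50 stones) carry
  visible Monte-Carlo error; Bayes factors near zero should be judged with
  replicate seeds.
* The OU residual kernel assumes an ultrametric tree (distance-based
  form); non-ultrametric inputs are flagged upstream.
* `run_all()` reports nominal p-values across its PGLS suite without
  multiplicity adjustment, matching standard practice for this analysis
  family; the report says so rather than silently correcting.
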