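---
title: "Multifamily Bayesian QTL mapping for doubled haploid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifamily Bayesian QTL mapping for doubled haploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfqtl)
```

## The problem

Breeding programs often genotype several biparental populations that share
one elite parent.  Analyzing such families jointly has two payoffs: QTL
detection borrows strength across families, and the analysis reveals *which*
donor parents carry an allele different from the elite parent's — exactly
the information needed to plan allele pyramiding.  `mfqtl` implements this
joint analysis for doubled haploid (DH) families: every line is fully
homozygous, so each genotype is a single (doubled) recombinant gamete and
dominance is absent by construction.

## The model

For line $j$ of family $i$ the season-adjusted phenotype is modelled as

$$y_{ij} = \mu_i + \sum_{l=1}^{N} s_{il}\, u_{ijl}\, a_l + e_{ij},
\qquad e_{ij} \sim N(0, \sigma_e^2),$$

where the genome is partitioned into 1-cM intervals, $u_{ijl} \in \{-1,+1\}$
codes the interval genotype (+1 = common-parent allele), $a_l$ is the
additive effect of a QTL in interval $l$, and $s_{il} \in \{0,1\}$ indicates
whether QTL $l$ segregates in family $i$ (a cross whose two parents carry
the same allele contributes no information about that QTL, and $s_{il}$
lets the model express exactly that).  The number of QTLs $N$ and their
interval positions are themselves unknowns.

### Priors and the sampler

The original description of this model class leaves the priors and chain
settings open, so the ones used here are deliberate, documented choices
(all exposed in `scan_priors()` / `mcmc_control()`):

* $N \sim \text{Poisson}(\lambda = 2)$ truncated at $N_{\max} = 20$, with at
  most one QTL per interval and positions uniform over unoccupied
  intervals.  $\lambda$ plays the role of a weak Occam prior; the data can
  push $N$ well above or below it.
* $a_l \sim N(0, \sigma_a^2)$ with $\sigma_a^2$ defaulting to the phenotypic
  variance — weakly informative on the scale of the trait.
* $s_{il} \sim \text{Bernoulli}(\pi_s = 0.5)$ independently.  Setting
  $\pi_s = 1$ fixes every indicator and reduces the model to ordinary
  Bayesian interval mapping on the pooled families (used as an internal
  consistency check against least squares).
* $\sigma_e^2$ carries the improper scale prior $1/\sigma^2$.

One MCMC sweep performs Gibbs updates of $\mu_i$, each $s_{il}$ (Bernoulli
from the conditional likelihood ratio), each $a_l$ (conjugate normal) and
$\sigma_e^2$ (scaled inverse chi-square); then a reversible-jump birth or
death move — birth proposes a uniformly chosen unoccupied interval with
effect and indicators drawn from their priors, so the acceptance ratio
collapses to the likelihood ratio times $\lambda/(N{+}1)$ and the proposal
correction — and finally one position move per QTL to a random unoccupied
interval.  The per-interval posterior probability $p_l$ is the occupancy
frequency of the retained samples; per-chromosome *QTL intensity* is
$\sum_{l \in \text{chr}} p_l$, and the sum of all intensities equals the
posterior mean of $N$ exactly (a bookkeeping identity the tests assert).

Chain defaults are 20,000 sweeps, 2,000 burn-in, thinning 10.  The tests
and the acceptance script run desk-scale chains (600–2,000 sweeps on
genomes of 120–4,050 intervals with 150–564 lines); at those sizes a
single strong QTL is localized within 5 cM with segregation probabilities
above 0.9, which is what the property suite asserts.

### Significance by permutation

The genome-wide 5% threshold for QTL intensity is the 5th-highest maximum
chromosome intensity over 100 scans of permuted phenotypes
(`permutation_threshold()`, the $\lceil \alpha B \rceil$-th order statistic
in general).  Phenotypes are shuffled *within* family so that the family
means $\mu_i$ — which are not part of the null hypothesis — are preserved.
Because rerunning full chains 100 times dominates runtime, permutation
chains may be shortened by an integer factor (default 4); the output flags
this.

### Calling and summarizing QTLs

A chromosome is declared to carry a QTL when its intensity exceeds the
threshold, and two QTLs when it exceeds twice the threshold; in the latter
case the boundary is the interior interval of minimum $p_l$ such that both
sides still sum above the threshold, falling back to a single call (with a
warning) when no such boundary exists.  Reported position and effect are
$p_l$-weighted averages.  The averages are taken over the contiguous run of
intervals with $p_l > 0.01$ containing the posterior mode rather than over
the whole chromosome: a variable-dimension sampler leaves a thin film of
prior-driven occupancy across all intervals, and on the small test genomes
that film would otherwise dilute the summaries (on a ~4,000-interval
genome its per-interval level is negligible).

The tables this package mirrors print a per-QTL "contribution" without
defining it; `qtl_contribution()` therefore uses this package's own
explicit definition,

$$\text{contribution} = \frac{\sum_{l \in \text{region}} p_l\, \bar s_l\,
\hat a_l^2\, \widehat{\text{Var}}(u_l)}{\widehat{\text{Var}}(y)},$$

with $\bar s_l$ the across-family mean segregation frequency.  It recovers
the obvious limits (0 for a null QTL, 1 for a noiseless single QTL, ~0.5
for $a = 1$, $\sigma_e = 1$, $\text{Var}(u) = 1$), but exact agreement with
any published contribution column is not claimed.

## Season adjustment

Multi-environment plot values are corrected by a single joint additive
least-squares fit `value ~ line + environment` (no interaction) with a
sum-to-zero constraint on environment effects, then averaged per line
(`adjust_for_environment()`; a `per_family` switch fits families
separately).  Under this constraint, adding a constant shift to one
environment moves all adjusted values by a common constant (the shift's
share of the grand mean) while leaving every between-line difference
untouched — which is the invariance that matters downstream, and what the
tests assert.  The correction is idempotent: re-adjusting corrected data
estimates environment effects of zero.

## Maps, the interval grid, and imputation

* `estimate_rf_dh()`: in DH lines the recombination fraction between two
  markers is the discordance fraction among jointly scored lines.
* `build_joint_map()` orders markers by physical position and pools
  per-family recombinant counts at each adjacent gap (the maximum-likelihood
  estimate under a shared recombination fraction, and strictly more
  efficient than averaging per-family estimates); gaps are converted with
  the Kosambi function, families in which a marker does not segregate
  contribute nothing at gaps involving it, and a pooled fraction at or
  above 0.5 is capped at 0.49 with a warning.
* `interval_grid()` anchors 1-cM, half-open `[start, end)` intervals at
  0 cM per chromosome and keeps the final partial interval; the interval
  index runs genome-wide.  A marker lying exactly at the chromosome end is
  assigned to the last interval.
* `impute_interval_genotypes()` evaluates each interval at its midpoint.
  Between two scored flanking markers the two-step no-interference Markov
  chain gives $P(Q \mid g_L, g_R)$ and $u = 2P - 1$; beyond the terminal
  scored marker the single nearest marker conditions the locus,
  $u = g\,(1 - 2r)$ — a documented choice, since the end-of-chromosome
  behaviour of imputation is not specified by the source material.  An
  interval containing a scored marker takes the observed code verbatim.
  Lines with no scored marker on a chromosome get $u = 0$ there (with a
  warning): zero is the Mendelian expectation and contributes no
  information to any QTL on that chromosome.  The expectation $u \in
  [-1, 1]$ feeds prediction; the sampler uses the maximum-probability hard
  call by default (the model defines $u \in \{-1, +1\}$), switchable via
  `mcmc_control(genotype = "soft")`.

## Prediction and cross-validation

The prediction equation weights every interval's estimated effect by its
posterior probability:
$\hat y_i = \hat\mu + \sum_{l=1}^{m} p_l\, u_{il}\, \hat a_l$.
Although the printed form of this equation carries a single intercept, the
fitting model has per-family means, and validation lines come from the
same families; `predict()` therefore uses the family-specific intercept
when a line's family is known and the size-weighted grand mean otherwise
(switchable with `use_family_means = FALSE`).  Soft (expected) interval
genotypes are used for prediction because the expectation minimizes
squared error given the flanking data.

`crossvalidate()` deals lines into `k` near-equal folds (564 lines at
`k = 6` give folds of exactly 94), refits the full scan on the training
folds — the source material does not say whether the original analysis
refitted per fold; refitting is the conservative reading — and reports the
per-fold Pearson correlation between predicted and observed adjusted
values with mean and SD.

## Ideotype construction and genotype simulation

`define_regions()` turns a posterior field into QTL regions: maximal runs
of intervals with $p_l > 0.01$, where a sub-threshold run flanked on both
sides (same chromosome) by such runs is absorbed, merging its neighbours —
the only reading of the published region rule that produces contiguous
blocks.  `build_ideotypes()` fixes the favorable allele in every region
for Ideotype 1 and then releases the regions carrying only the secondary
trait one at a time in ascending order of contribution (ties break by
region order); regions containing a primary-trait QTL are never released,
and when a region carries QTLs of both traits with conflicting favorable
alleles, the primary trait wins.  Applied to the bundled region table,
this derivation reproduces the published ten-ideotype A/B/– ladder
exactly, which the acceptance suite asserts.

`generate_genotypes()` samples whole-genome interval genotypes from the
no-interference Markov chain along each chromosome (per-gap recombination
fractions from the inverse Kosambi function of midpoint spacing),
conditioned on all fixed blocks by backward filtering / forward sampling —
an exact Markov bridge, chosen over rejection sampling because it never
rejects and is exact for a two-state chain.  Fixed multi-interval regions
are held as single haplotype blocks (no internal recombination), matching
how the published ladder treats each region as one unit.  Two adjacent
fixed blocks with opposite alleles and zero recombination between them are
reported as infeasible.  Marginal allele frequencies at free intervals
relax toward 1/2 as the phase-retention product $\prod_j (1 - 2 r_j)$
decays with map distance from the nearest fixed block — there is no sharp
"unlinked" cutoff, and the tests check the exact decay law rather than a
distance rule of thumb.

## The synthetic data generator

`simulate_dataset()` emulates the study system the package is built
around: three DH families of 188 lines sharing one parent, 21 wheat
chromosomes whose default lengths average the three published
per-population map totals (~3,944 cM genome-wide), markers every 5 cM
(~860 genome-wide, matching the joint map's marker count), biallelic QTLs
with family-specific segregation flags, additive season effects,
unreplicated plots with Gaussian residuals, and uniform missingness
(no missingness mechanism being stated, uniform is the neutral choice).
Meiosis is one Bernoulli recombination per marker gap with probability
from the inverse Kosambi function, independently across gaps — no
crossover interference, which keeps the simulator exactly consistent with
the imputation Markov chain and the bridge sampler.

What the generator does **not** emulate: genotyping error, segregation
distortion, heterozygosity, epistasis, genotype-by-season interaction,
non-Gaussian residuals, or a nonuniform marker density.  Passing tests
therefore show that the estimation machinery is correct under its own
model assumptions at realistic sizes; they cannot show robustness to the
ways real field data violate those assumptions.

True genetic architectures are free parameters (the source material does
not state them).  The study-scale emulation used by the acceptance checks
is a polygenic trait — 150 loci with random effect signs spread over the
full genome — with the residual SD calibrated against the *realized*
genetic variance so that season-adjusted heritability is exactly 0.63.
Random signs matter: linked loci with same-sign effects covary positively
and silently inflate the realized genetic variance well above the sum of
per-locus terms.  A handful of large-effect loci would be the wrong
stand-in here: at 564 lines a trait driven by eight strong QTLs is
predicted with accuracy near $\sqrt{h^2}$, well above the published
cross-validation range, whereas a polygenic architecture on the full-size
genome reproduces it.

## Numerical choices and degenerate inputs

* Kosambi transforms are closed-form (`0.25 log((1+2r)/(1-2r))` Morgans
  and its tanh inverse); the identity holds to 1e-10 over 0–100 cM.
* Hard-call ties ($u = 0$) resolve to +1 deterministically.
* `marker_heritability()` fits the one-variance-component REML through a
  single eigendecomposition of the observation-level relatedness matrix,
  profiles the likelihood on an $h^2$ grid refined by golden-section
  search, and reports a 95% profile-likelihood interval.  It accepts plot-
  level replicates (through the `lines` argument) or line-level values;
  with identity kinship and balanced replicates it reproduces the ANOVA
  variance components, the oracle the tests use.  The exact plot-level
  likelihood and interval method of the package the study cites are not
  described there, so recovery is validated by simulation, and matching
  any published heritability table exactly is not claimed.
* Correlation matrices report raw two-sided t-test p-values plus a
  Holm-adjusted copy; the published figures say only "multiple comparison
  tests", so the procedure is named explicitly here.
* All randomness descends from explicit integer seeds; the pipeline
  derives one seed per stage from the master seed by a fixed offset, so
  stages rerun independently and reruns are byte-identical (asserted on
  the written artifacts).

## Known limitations

* The sampler is a faithful reconstruction of a model whose original
  implementation details (proposal mix, priors, chain lengths) are not
  public; posterior fields will agree in structure, not bit-for-bit.
* One QTL per interval bounds $p_l \le 1$ by construction but makes the
  1-cM grid resolution a hard floor on separability of linked QTLs.
* The contribution definition is this package's own (see above).
* Heritability uses a single genetic variance component; maternal or
  family-specific variances are not modelled.
* Permutation chains default to quarter length; thresholds inherit the
  corresponding Monte Carlo noise (the output records both the maxima and
  the shrink factor so this is auditable).
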