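---
title: "Mapping selection in variety panels with RALLY and parametric control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selection in variety panels with RALLY and parametric control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Historical panels of crop varieties — sets of lines released over several
decades, genotyped at thousands of markers — carry a record of what
breeders selected for. An allele favoured by sustained selection rises in
frequency across release years; an allele subject only to drift wanders.
`rallyscan` maps the genomic regions showing sustained frequency change
(quantitative selection loci, QSLs) without using any trait data, and then
relates those regions to traits through variance partitioning and
marker-effect models.

## The RALLY model

For marker $i$, let $z$ be a variety's allele count (0/1/2) and $X_R$ its
year of release. RALLY fits a two-trial binomial logistic regression

$$\mathrm{logit}\, p_i = \mu_{R,i} + \beta_{R,i} X_R,$$

so $\beta_{R,i}$ is the per-year change in log-odds of carrying the coded
allele and $\mu_{R,i}$ the log-odds at year zero. A Wald statistic
$Z = \hat\beta/\mathrm{SE}$ and a two-sided normal $p$ follow. Fitting is
IRLS, shared across all markers of a panel (the design matrix is common,
only the response changes), with years centered internally for stability
and the intercept reported on both the centered and the calendar origin.
Inbred panels make the two-trial binomial natural: a fully inbred line
contributes two identical Bernoulli trials, and residual heterozygotes
(count 1) contribute half weight. Countries of origin enter as dummy
covariates when available; countries with fewer than 5 varieties are
merged into "other" to avoid separation.

Monomorphic markers are flagged and skipped. Complete separation (the
allele splits perfectly by year) has no finite MLE; fits whose centered
slope exceeds 15 in absolute value are flagged as non-converged and get no
$p$ value. The per-test threshold is Bonferroni, $\alpha/m$ over the
markers actually fitted after the minor-allele-frequency filter
(default maf $\ge$ 0.01).

## Parametric control

Population structure and drift inflate the naive statistics: under the
null, $Z$ at a drifting marker behaves like $N(\delta, \sigma^2)$ with
random sign rather than $N(0,1)$. Parametric control (PC) estimates
$(\delta, \sigma)$ from a *null marker set* — markers whose model-predicted
frequency change over the observed year span, $|\Delta\hat p|$, falls
below a threshold $t$ (default 0.20) — by maximizing the equal-weight
two-component composite likelihood of $\pm\delta$ normals, and
standardizes every marker as

$$Z_{adj} = \frac{|Z| - |\hat\delta|}{\hat\sigma}.$$

Because only large $|Z|$ is evidence of selection under the folded null,
the adjusted $p$ is upper-tail one-sided by default (a `tail = "two"`
switch doubles it). The classical genomic-control factor
$\lambda = \mathrm{median}(Z^2)/0.4549364$ is reported alongside; the
constant is the exact $\chi^2_1$ median rather than the conventional
rounded 0.456.

### Numerical behaviour of the folded-normal likelihood

The composite likelihood is well behaved when $\delta/\sigma \gtrsim 1.5$
(parameter recovery to better than $\pm 0.03$ at $10^5$ statistics) but is
*nearly unidentifiable along the ridge* $\delta^2 + \sigma^2 =
\overline{z^2}$ as $\delta \to 0$: the Fisher information for $\delta$
vanishes there and the MLE of $\delta$ converges at rate $n^{-1/4}$. Two
practical consequences, verified against a grid-search oracle:

* on a true $N(0,1)$ null, $\hat\delta$ may land anywhere in roughly
  $[0, 0.3]$ at $n = 10^5$ while $\hat\delta^2 + \hat\sigma^2$ matches the
  second moment to numerical precision — the *adjustment* is stable even
  when the split between $\delta$ and $\sigma$ is not;
* refitting the folded model to already-adjusted statistics does not
  return $(\hat\delta, \hat\sigma) \approx (0, 1)$, because the adjusted
  values are no longer a sign-symmetric folded-normal sample; the refit
  slides along the ridge. The reliable self-consistency diagnostic is
  $\lambda_{GC}$ of the adjusted null statistics, which stays within
  $[0.9, 1.1]$.

The optimizer is multi-start box-constrained quasi-Newton (L-BFGS-B) with
$\delta \ge 0$ and $\sigma$ bounded away from zero; a fit at the $\sigma$
bound (a point-mass degenerate input) is flagged.

## The breeding-program simulator

The simulator provides panels in which the truth is known. Its defaults
are the study conditions: a 10-chromosome genome of 100–280 cM with one
marker per 0.1 cM (19,000 markers); 32 inbred founders; 32 causal QTLs,
two at each founder frequency $k/32$, $k = 1..16$, with tier effects
4/3/2/1 for frequency classes $\{1\}$, $\{2,3\}$, $\{4..7\}$,
$\{8..16\}$, rescaled so the founder-frequency additive variance
$\sum p(1-p)\beta^2$ is exactly 1 against residual variance 1
(heritability 0.5, largest per-QTL heritability 0.0314). Each generation
makes 16 bi-parental crosses among 32 parents drawn from the pool 6–10
generations back, derives 100 F6 RILs per cross (F2 plus four single-seed
selfings; crossovers Poisson/no-interference), keeps the top 2 by
phenotype (selected) or a random 2 (unselected), discards 15 burn-in
generations, and retains 8 random varieties per generation for 50
generations — a 400-variety panel with year = generation index.

Founder haplotypes are the one component the original study obtained from
a coalescent engine; here they come from a neutral-SFS generator:
derived-allele counts follow $P(k) \propto 1/k$, and the carrier set
persists along the chromosome with probability 0.98 per 0.1 cM step, so
founder LD decays on the few-cM scale relevant to the ~5 cM detection
limit. This choice emulates the *scale* of founder LD but not its *shape*:
within a persistence block founder LD is exactly $r^2 = 1$, where
coalescent haplotypes would show a smooth decay below 1. Selected-panel
sweeps therefore drag more perfectly-linked neighbours to significance,
and the small number of independent founder lineages makes drift inflation
stronger (typical $\lambda_{GC}$ near 4). Tests and the acceptance study
consequently reproduce the published simulation *pattern* — selected
panels light up near QTLs, unselected panels are clean after PC,
correction strength grows as the null-set threshold falls — at larger
absolute counts than the published means, which is expected for a
different founder engine and is why those comparisons are tolerance-band.
Residual F6 heterozygosity follows the Mendelian closed form
$(1/2)^5 \approx 0.031$ (an F2 is already half heterozygous; four
selfings halve that four more times).

The marker-exclusion rules before simulated scans mirror the study design:
drop maf < 0.01, the QTL markers themselves, and markers with $r^2 > 0.99$
to any QTL.

## Downstream analyses

**GWAS baseline.** A mixed linear model with VanRaden kinship ($2p$
centering; the literal single-$p$ centering of the printed formula is
available via `centering = "p"`), year covariate, and a per-marker fixed
effect. Variance components are estimated once on the null model by
spectral (single-kinship) REML and reused for every marker (the
P3D/EMMAX convention); per-marker effects are then generalized least
squares with Wald tests.

**Hitch-hiking detection limits.** With selection represented as a forced
QTL-frequency trajectory (logit-linear or linear to 31/32 over 50
generations), conditional marker frequencies relax toward the marginal at
rate $\theta$ per generation, $f'(M|Q) = (1-\theta)f(M|Q) + \theta f(M)$
(Haldane map function by default, Kosambi available). Finite-sample power
is estimated by binomial sampling of 8 individuals per generation feeding
the RALLY fit. The initial haplotype configurations are enumerated on a
1/8-step grid consistent with 32-founder granularity.

**QSL grouping and local heritability.** Significant markers cluster
around focal (most significant) markers by $r^2 > 0.2$ within the focal
chromosome, with a minimum group size of 10 and transitive-closure merging
of overlapping groups. Each group's trait content is measured by a
two-kinship mixed model — one GRM from the group's markers, one from the
rest — fitted by average-information REML with EM fallback steps and
non-negativity constraints; $h^2_l = \sigma^2_{ga}/(\sigma^2_{ga} +
\sigma^2_{gb} + \sigma^2_\varepsilon)$. Groups passing $h^2_l > 0.001$
are refitted jointly (one random term per group plus background), and the
joint shares are reported. Nonzero tests use the boundary-corrected
likelihood-ratio null, the half-half mixture of a point mass and
$\chi^2_1$.

**Marker effects and direction concordance.** Ridge (RR-BLUP: penalty
$\lambda = \sigma^2_\varepsilon/\sigma^2_u$ from REML, solved through the
$n \times n$ dual) and multi-task LASSO (glmnet `mgaussian`, shared
support across traits, seeded 10-fold CV) estimate marker effects on
$-1/0/1$ coding. The direction product $\tilde d = \mathrm{sign}(u) \cdot
\mathrm{sign}(\hat\beta_R)$ says whether the allele rising over years
raises ($+1$) or lowers ($-1$) the trait; markers are classed by
PC-adjusted significance (below Bonferroni / between Bonferroni and 0.05 /
above 0.05). Trait-pair interactions among rising alleles use the
Yates-corrected $\chi^2_1$ on the $2\times2$ direction table — the
continuity correction is what reproduces the published worked rows
(FT/YLD $\to 4.435$, LODG/HT $\to 20.083$) — tested for LASSO only,
since ridge effects are not independent, at Bonferroni over the
$\binom{T}{2}$ pairs ($-\log_{10} p = 3.121$ for 12 traits).

**Multivariate breeder's equation.** Per-trait genetic trends
$\Delta Z$ (OLS slope of GBLUP genetic values on year), genetic and
phenotypic covariances $(G, P)$, and the chain $\beta_{sel} = G^{-1}\Delta
Z$, $S = P\beta_{sel}$, $i = S/\sqrt{\mathrm{diag}(P)}$. Genetic
covariances come from the variance-of-sum identity
$\mathrm{cov}_g(y_1,y_2) = \{V_g(y_1+y_2) - V_g(y_1) - V_g(y_2)\}/2$
applied to single-kinship REML fits — a deliberate design choice, since no
installed dependency provides bivariate GRM REML and the identity is exact
for the model. $G$ is projected to the nearest positive semi-definite
matrix (eigenvalue clipping, Frobenius shift logged) when sampling noise
pushes it indefinite. Each parameter splits into a *direct* part (the
trait's own diagonal pathway, e.g. $G_{kk}\beta_k$) and an *indirect*
remainder; this additive split is our interpretation of the
direct/indirect decomposition, stated as such in output headers. The
three-trait validation simulates one generation of index truncation and
compares gradients computed from the realized differential with true
covariances ("true"), from the realized response with true $G$
("realized"), and with a sampled $G$ ("estimated"); the estimated version
correlates worse with truth than the realized one, which is the method's
known practical limitation.

## Problem sizes and determinism

Module tests run on small genomes (hundreds of markers) with seeded RNG.
The replicate study behind the simulation-pattern checks uses 3 panel
pairs at the default 19,000-marker genome in the test suite and 10 pairs
in `scripts/acceptance.R`; one pair costs roughly a minute on one core.
The boundary-mixture LRT calibration uses n = 100 and 200 null
replicates; the two-kinship recovery check uses n = 400 and 5 replicates.
All REML fits are deterministic from fixed starting values (equal shares
of phenotypic variance); AI-REML converges on $|\Delta \ell| < 10^{-6}$
with a 200-iteration cap and EM fallback whenever an AI step would not
improve the restricted likelihood.

## Known limitations

* Founder LD is blockwise, not coalescent; absolute significance counts
  in simulated selected panels exceed published means (see above), so
  cross-engine comparisons should be read on the pattern, not the count.
* PC assumes the null set is selection-free; when selection is weak and
  pervasive, $|\Delta\hat p| < t$ admits selected markers and the
  correction overshoots. This is inherent to the method, not the
  implementation.
* The hitch-hiking recursion is infinite-population by construction;
  drift enters only at the sampling step.
* Missing genotypes are complete-case per marker in scans and
  mean-imputed in kinship and penalized-regression matrices; no genotype
  imputation is attempted.
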