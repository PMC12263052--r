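---
title: "Two-sample MR along a causal chain: models, defaults and design choices"
author: "mrchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR along a causal chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchain)
```

# The problem

Observational associations between molecular traits (circulating lipid
species, immune cell phenotypes, inflammatory proteins) and complex disease
are confounded and can run in either direction. Two-sample Mendelian
randomization (MR) uses genetic variants as instrumental variables: a
variant that robustly shifts an exposure, is independent of confounders,
and affects the disease only through that exposure identifies the causal
effect of the exposure from GWAS summary statistics alone. `mrchain`
implements the full screening design of such a study: panels of candidate
exposures tested against a disease outcome in both directions, exclusion of
traits with reverse causation, and a two-step decomposition of each
surviving exposure's effect through candidate mediators.

# Estimators

Let $\hat\beta_{Xj}, \hat\beta_{Yj}$ be the effects of instrument $j$ on
exposure and outcome with standard errors $\sigma_{Xj}, \sigma_{Yj}$, after
harmonization to a common effect allele. The per-variant Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (the exposure-side term is ignored, as
usual for summary data; a second-order option exists in `waldRatios()`).

**IVW.** The inverse-variance weighted estimate is weighted least squares
of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with weights
$1/\sigma_{Yj}^2$:
$$\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}/\sigma_{Yj}^2}
{\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2},\qquad
\mathrm{se}_{fixed} = \Big(\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2\Big)^{-1/2}.$$
Cochran's $Q=\sum_j(\hat\beta_{Yj}-\hat\theta\hat\beta_{Xj})^2/\sigma_{Yj}^2$
is referred to $\chi^2_{k-1}$. The headline flavor is multiplicative random
effects: the SE is inflated by $\sqrt{Q/(k-1)}$ only when $Q/(k-1)>1$. This
is conservative and never narrows the fixed-effect interval; the price is a
mildly sub-nominal rejection rate under homogeneity (the null-calibration
test shows ~0.04 at $\alpha=0.05$), which is why the exactly-calibrated
fixed flavor is also reported.

**MR-Egger.** The same regression with an intercept, after orienting every
variant so $\hat\beta_{Xj}\ge 0$. The slope is robust to directional
pleiotropy under the InSIDE assumption; the intercept estimates the mean
direct (pleiotropic) effect per instrument. SEs carry the multiplicative
scale $\max(1,\sqrt{RSS_w/(k-2)})$.

**Weighted median.** Ratios are ordered; with normalized inverse-variance
weights $w_j$ and cumulative midpoints $p_j=S_{j-1}+w_j/2$, the estimate
interpolates the ordered ratios at $p=0.5$. Consistent when valid
instruments carry $>50\%$ of the weight.

**Weighted mode.** The argmax of a Gaussian kernel density over the ratios
(weights $1/\mathrm{se}(\hat\theta_j)^2$) on a 512-point grid spanning the
ratio range. Bandwidth is $\phi\times 0.9\min(s, IQR/1.349)k^{-1/5}$ with
$\phi=1$ by default. We use the $IQR$ rather than the MAD in the modified
Silverman rule because the MAD collapses to zero whenever a bare majority
of ratios coincide — exactly the regime the mode estimator is for.

Median and mode SEs come from a parametric bootstrap (default 1000 draws;
per-variant effects redrawn from normals at the observed SEs) under a
caller-supplied seed. P-values are two-sided normal throughout — the
summary-data convention — and are documented as approximate when $k$ is
small; effects are reported both on the log-odds scale and as
$OR = e^{\hat\theta}$ with 95% limits $e^{\hat\theta \pm 1.959964\,se}$.

**Multivariable IVW** regresses outcome effects on several exposures'
effects jointly (no intercept, weights $1/\sigma_{Yj}^2$), giving each
exposure's direct effect conditional on the others; with one exposure it
reduces exactly to random-effects IVW.

# Instrument selection

The selection pipeline runs in a fixed order, each step shrinking the set:

1. association p-value $< 5\times10^{-5}$ (strict), the conventional
   relaxed threshold for molecular exposures with modest GWAS;
2. removal of variants on a static confounder exclusion list (the
   reproducible stand-in for database lookups such as PhenoScanner);
3. greedy LD clumping: repeatedly take the smallest-p remaining variant
   (ties broken lexicographically by id for determinism) and prune
   variants with $r^2 >$ 0.001 **and** distance $<$ 10,000 kb on the same
   chromosome. Both conditions are required — a deliberate reading of the
   usual "r² and window" phrasing; with no LD matrix supplied, variants
   are treated as independent. The package never computes LD itself.
4. instrument strength $F = (\hat\beta/\mathrm{se})^2 > 10$ (strict). The
   squared Wald z needs no sample size or variance-explained input and is
   the standard summary-data approximation.

Harmonization aligns the outcome to the exposure's effect allele, flipping
signs for swapped codings and recognizing strand complements. Palindromic
(A/T, C/G) variants cannot be strand-resolved from labels: they are
oriented by allele-frequency concordance and dropped as ambiguous when
either frequency is missing or inside [0.42, 0.58] (inclusive — the
conservative choice at the boundary). Every variant entering a pair is
accounted for exactly once: retained, or dropped with one reason.

# Screening and direction classification

Panel screening calls an exposure "significant" when the random-effects
IVW p-value is below $\alpha = 0.05$, nominal and uncorrected — matching
how such screens are usually reported; a Benjamini–Hochberg FDR column is
emitted alongside for users who want rigor over fidelity. Reverse MR reuses
identical machinery (and, by default, the same instrument criteria — the
relaxed threshold is a config knob) with the disease as the exposure. The
direction label is the truth table of the forward and reverse significance
calls, and bidirectional pairs are excluded from mediation: a trait the
disease itself alters cannot be a clean exposure or mediator.

# Mediation

For an eligible exposure $X$, mediator $M$ and outcome $Y$, with
univariable estimates $\hat\tau$ (total, $X\to Y$), $\hat\alpha$
($X\to M$) and $\hat\beta$ ($M\to Y$):

* **product of coefficients** (primary): indirect $=\hat\alpha\hat\beta$,
  $\mathrm{se}^2 = \hat\beta^2\mathrm{se}_\alpha^2 +
  \hat\alpha^2\mathrm{se}_\beta^2$ (delta method, independent samples);
* **difference**: indirect $=\hat\tau-\hat\gamma$ where $\hat\gamma$ is
  the exposure's coefficient from multivariable IVW over the union of the
  $X$ and $M$ instrument sets, $\mathrm{se}^2 =
  \mathrm{se}_\tau^2+\mathrm{se}_\gamma^2$ (conservative; the shared total
  term is propagated into the proportion's SE).

The proportion mediated is indirect/total with a delta-method SE.
Cross-fit covariances are set to zero (three non-overlapping samples
assumed). Proportions outside $[0,1]$ or with an indirect effect of
opposite sign to the total are flagged, never truncated. A mediation
estimate is produced only when both chain steps pass the $\alpha$ gate
(X→M and M→Y each significant); the product method is primary because it
needs only the univariable fits the two-step design actually describes,
while the difference method's "direct effect" is interpreted as the
multivariable-MR coefficient — the one defensible reading when the source
design does not say.

When the total effect is exactly zero the proportion is undefined; the
estimate is returned with the indirect effect intact, `NA` proportion
fields and a classed warning rather than an error, so panel runs never
abort on a degenerate row.

# The synthetic generator

`simulateTriplet()` draws a GWAS summary triplet from a linear structural
model $X \to M \to Y$ with a direct $X \to Y$ path. Each trait owns a
disjoint block of `nSnps` candidate instruments (disjointness keeps the
two-sample assumptions clean and isolates estimator behavior from overlap
bias). Block effects are scaled so each block explains exactly
`exposureH2` of its trait's variance; downstream effects follow the
structural equations, with the implied total effect
$\theta_{direct}+\theta_{XM}\theta_{MY}$. Observed effects add sampling
noise with $\mathrm{se} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$,
the standardized-trait approximation that we also apply, documented as an
approximation, to the binary outcome's log-odds. All randomness flows from
one mandatory seed through derived sub-streams, so a dataset's noise can
be reproduced independently of the others. The generator emits the
canonical TSV, making simulated studies indistinguishable from real
inputs to every pipeline stage.

Pleiotropy options add per-variant direct effects $\alpha_j$ to the
exposure block's outcome effects: `balanced` draws
$\alpha_j\sim N(0,\mathrm{scale}^2)$, `directional`
$N(\mathrm{scale},\mathrm{scale}^2)$. Directional effects are applied
relative to the exposure-increasing allele ($+\mathrm{sign}(b_j)\alpha_j$):
orientation-independent effects would be symmetrized by Egger's
$\hat\beta_X \ge 0$ convention and undetectable by construction.

The outcome always carries its own instrument block — a disease GWAS has
its own loci — and `reverseTheta` scales that block's propagation into the
exposure (0 = purely forward causation). This keeps reverse-MR
calibration well defined: without outcome-side instruments most reverse
fits would simply fail for lack of instruments.

## Default design, and why

| parameter | default | rationale |
|---|---|---|
| `nSnps` | 100/block | enough instruments for all estimators after selection |
| `exposureH2` | 0.05 | typical molecular-trait instrument heritability at a relaxed threshold |
| `nX` | 500,000 | exposure instruments strong: median $F \approx h^2 n/\mathrm{nSnps} = 250$ |
| `nM` | 100,000 | mediator supplies its own strong instruments (median $F \approx 50$) |
| `nY` | 15,088 | the case-count scale of a biobank disease phenotype |
| $\theta_{XM},\theta_{MY},\theta_{direct}$ | 0.4, 0.5, 0.3 | canonical recovery scenario: total 0.5, proportion mediated 40% |
| `mafRange` | (0.05, 0.5) | common variants |
| `pleiotropyScale` | 0.02 | detectable directional shift at 100 instruments |

`nY` matters more than it looks. With a very large outcome GWAS, exposure
instruments reach the selection threshold *in the outcome's own scan*;
used as "outcome instruments" in reverse MR, they carry ratio
$1/\theta_{total}$ and make a purely forward pair look bidirectional. At
the case-count scale the leakage non-centrality is ~1.9 and reverse
screens of forward-only models classify `forward_only` in ≈97% of
replicates — the qualitative behavior real screens show.

## What the generator does and does not emulate

It emulates: sampling noise consistent with stated sample sizes, selection
effects (winner's curse), weak-instrument attenuation, horizontal
pleiotropy, reverse causation, and cross-trait instrument leakage. It does
**not** emulate LD structure (clumping is exercised with hand-written LD
fixtures), allele-frequency drift between cohorts, sample overlap between
the three GWAS, population stratification, or binary-trait
liability-scale subtleties. Passing calibration tests therefore supports
the estimators' arithmetic and the pipeline's logic, not robustness to
those un-modeled features of real data.

## A measured limitation of two-step mediation

Because the mediator is heritable through the exposure, a large mediator
GWAS co-selects exposure-block SNPs as mediator instruments (about 17% of
the M→Y instrument set at the defaults). Those SNPs reach the outcome
through the direct path too, so their M→Y ratio is
$\theta_{total}/\theta_{XM} = 1.25$ rather than $\theta_{MY} = 0.5$,
inflating the M→Y estimate to ≈0.55 and the recovered proportion mediated
to ≈0.44 (truth 0.40); the total effect is simultaneously attenuated ~1.5%
by winner's curse. This is a property of univariable two-step mediation
itself — the design decision this package follows — not of the
implementation; mediator-adjusted (multivariable) step-2 fits or Steiger
filtering would reduce it, and both are deliberately out of scope. The
difference method, whose multivariable fit conditions on the exposure, is
less affected, which is itself a reason both are reported.

# Numerical choices

* Tie-breaks: duplicate variants on read keep the smallest p; clumping
  ties on p fall back to lexicographic id order. Both make the pipeline a
  pure function of its inputs.
* Degenerate inputs: a zero exposure effect makes the Wald ratio
  undefined and raises a classed error naming the variant; $k=1$ pairs
  report IVW only ($Q$ has 0 df and an `NA` p); methods needing $k\ge3$
  are recorded as skipped with the reason rather than failing the suite.
* The weighted-mode grid is fixed at 512 points between the extreme
  ratios; all-equal ratios short-circuit to the common value.
* P-values are floored at the smallest positive double so they remain in
  $(0,1]$.
* Full-precision serialization uses `%.17g`, making TSV round trips
  bit-exact; display columns round to 3 decimals (OR, CI, p) and
  percentages to 2, the conventions of published forest plots.
* Test and calibration problem sizes — 500 null replicates, 500 balanced-
  pleiotropy replicates, 200 recovery replicates, 100 direction-
  classification replicates, 100-SNP blocks — were chosen as the smallest
  designs whose Monte-Carlo error is well inside the tested bands.

# Known limitations

Beyond the generator's scope above: no MR-PRESSO outlier removal, no
Steiger direction filtering, no RAPS, no correction for sample overlap,
and no multi-mediator joint decomposition. The confounder-exclusion step
is a static list, by design: live database queries are irreproducible.
Printed-table consistency checks can only be as sharp as the published
rounding (a CI bound printed as "1" caps how precisely the p-value can be
recovered).
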