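---
title: "Predicting gene transcriptional state from histone-mark peak calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene transcriptional state from histone-mark peak calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Histone modifications (HMs) deposited around a gene's transcription start
site (TSS) carry much of the information that determines whether the gene
is transcribed. `markstate` turns ChIP-seq *peak calls* for a small panel
of HMs into a prediction of each gene's binary transcriptional state, and
— because the classifier is a plain logistic regression — back into an
interpretable, per-gene account of which marks pushed the prediction up
(activators) or down (repressors).

The pipeline has four stages.

**Featurisation.** Each gene receives an *input-field*: a window of
`l = 10000` bp placed symmetrically around its TSS (5 kb upstream, 5 kb
downstream), an expanded-promoter proxy. For every mark `h`, the peak
track is *localised* onto the field: position `i` of the length-`l`
vector `x` holds the signalValue (the peak caller's enrichment estimate)
of the peak covering that genomic position, 0 where no peak was called.
The field is then collapsed to a single nonnegative feature,
`phi[g, h] = max_i x_i` — the strongest enrichment of that mark anywhere
in the promoter window. Stacking gives the feature matrix `Phi` (genes ×
marks). The default panel is the five core HMs, in this column order:
H3K4me3 (promoter mark), H3K4me1 (regulative), H3K36me3 (structural),
H3K9me3 and H3K27me3 (repressors).

**Labelling.** Expression is measured in RPKM. A gene with abundance
`t_g <= t_bar` is OFF (class 0), otherwise ON; the default threshold is
the per-tissue median RPKM, which balances the classes; ties at the
threshold are OFF. An alternative `valley_threshold()` places `t_bar` at
the density minimum between the two modes of the typically bimodal RPKM
distribution (below).

**Fitting and evaluation.** Genes are split into ceil-balanced thirds
(train / validation / test; for 19,802 genes: 6601/6601/6600). An
unpenalised maximum-likelihood logistic regression is fitted on the raw
features of the training third. The peak *format* offered per mark
(narrowPeak / broadPeak / gappedPeak) is a hyperparameter: the
configuration maximising validation AUROC is selected, then the selected
model is evaluated on the untouched test third with AUROC, F1 (ON
positive, probability cutoff 0.5) and AUPR. The whole
tune-and-evaluate procedure is repeated over `k = 10` independent random
splits and summarised as mean ± sd.

**Interpretation.** For a gene `g`, the *regulative pattern* is the
weighted input vector `psi = phi_g * w` (element-wise), so the model's
logit decomposes exactly as `y_g = b + sum(psi)`. Positive components are
activating contributions, negative ones repressive; a per-mark Wald
z-test (`z = w/se`, two-sided) masks marks whose weight is not
significant at `alpha = 1e-4`. Patterns are matched against
ChromHMM-style emission vectors by Pearson correlation (the cosine of the
two mean-centered vectors); each chromatin state then collects the logits
of its matched genes, and states — or four coarser semantic groups — are
ranked by mean logit, which should recover the biological ordering
(active states high, repressed states low).

## Why these modelling choices

*Raw, unstandardised features.* The interpretation unit is
`psi = phi * w` against raw enrichments; standardising `Phi` would change
what `psi` means. For the same reason the fit is unpenalised by default,
which also keeps Wald inference valid. When the training data are
(quasi-)separable the MLE diverges; the fit then switches to a weakly
ridge-penalised IRLS solution (`lambda = 0.01` on the weights, none on
the intercept), keeps predictions usable, and flags the model so that
`significance_test()` refuses to report p-values from it. Separation is
detected from a non-converged fit, a near-zero residual deviance
(< 1e-6), or exploding weights/standard errors.

*Tie and ordering conventions.* Several steps need a deterministic
tie-break, chosen once and documented: equal validation AUROC between
dialect configurations resolves by the fixed preference narrow > broad >
gapped, then lexicographically; equal pattern–state correlation resolves
to the lowest state index; equal mean logits rank in label order. AUROC
uses midranks for tied scores, so it equals the fraction of concordant
(ON, OFF) pairs with ties counted one half.

*Split arithmetic.* Thirds are formed as `train = ceil(n/3)`,
`val = ceil((n - train)/2)`, `test = n - train - val` — the arithmetic
that yields the canonical 6601/6601/6600 partition at n = 19,802.

*Valley threshold.* The median rule is simple but partly arbitrary: with
a bimodal RPKM distribution it can cut through one of the components. Our
valley rule estimates a Gaussian-kernel density of `log(1 + RPKM)`
(default `nrd0` bandwidth), finds the two largest interior modes, and
puts the threshold at the lowest interior density minimum between them,
back-transformed with `expm1`. With fewer than two interior modes, or no
minimum between them, it falls back to the median with a warning. The
log1p scale is used because raw RPKM is extremely right-skewed and its
near-zero component would otherwise dominate the bandwidth.

*Hyperparameter space.* The search space is the Cartesian product of the
candidate peak formats per mark (3^5 = 243 configurations for the full
panel), searched exhaustively by default; above a configurable cap
(default 1024) a greedy per-mark coordinate search with restarts-free
sweeps is used instead. Selection refits on the training third only —
validation genes never touch the likelihood.

*Display normalisation.* Pattern bars (the m `psi` components *and* the
bias) are divided jointly by their largest absolute value, so the tallest
bar is ±1 and all relative signs/magnitudes survive. The bias is included
in the common scale because it is displayed on the same axis and conveys
the model's prior toward the inactive state. Normalisation is per gene; a
cohort-wide common scale can be obtained by rescaling externally, since
matching is invariant to any positive rescaling of a pattern.

*Zero patterns.* A gene whose field contains no peak of any mark has
`psi = 0`; its centered pattern is constant, so its correlation with
every state is undefined (reported 0). Such genes are assigned the
tie-break state but flagged `unmatched` and excluded from
gathering/ranking by default.

*Coordinates.* All I/O and interval arithmetic use 0-based half-open BED
intervals; GRanges conversions add/subtract 1 exactly once at the
boundary. gappedPeak block structure is parsed and carried but the outer
peak interval and its signalValue (column 13) are what featurisation
uses, matching how the localisation stage treats a peak as one enrichment
over one location. Fields that would start before position 0 are clipped
and zero-padded back to length `l`, with a warning.

## The synthetic cohort

`generate_fixture()` builds a fully self-contained cohort with planted
ground truth; it is what the tests and the acceptance script run on.

- Gene windows are placed at a fixed pitch of `l + gap` bp
  (default 10 kb + 4 kb) with sub-gap jitter, so input-fields never
  overlap and background peaks can be placed between windows without
  touching any field.
- Per gene and mark, with probability `1 - sparsity` (default 0.7) a
  planted enrichment is drawn log-normal(`log 3`, 0.5) — positive and
  right-skewed like real signalValue distributions — and realised as a
  "main" peak whose signalValue is exactly that enrichment, plus
  Poisson(0.7) decoy peaks at strictly lower signal. Max-featurisation of
  the fixture therefore recovers the planted feature matrix *exactly*,
  which the tests assert.
- The latent class is Bernoulli(sigmoid(`b* + w*·phi*`)) with default
  planted weights (0.8, 0.45, 0.6, −0.5, −0.9) following the
  activator/repressor semantics of the five core marks, and `b*` chosen
  to center the planted logit at zero (near-balanced classes).
- Expression is drawn class-conditionally: OFF genes log-normal around
  0.05 RPKM, ON genes around 50 RPKM, giving the bimodal shape both
  threshold rules need; a fixed threshold of 1.0 RPKM sits in the gap and
  recovers the latent class essentially always, while the median rule
  flips the handful of genes whose Bernoulli draw disagreed with the
  majority side of its logit.
- All three BED dialects are emitted for every mark (same calls,
  dialect-appropriate columns). Declaring an `informative_dialect` for a
  mark permutes the signalValues of the *other* dialects across peaks,
  creating label-uninformative decoy formats for selection tests.
- Emission fixtures draw U-shaped (Beta(0.4, 0.4)) emission rows and
  reject any row whose mean-centered cosine with an earlier row exceeds
  0.8, so planted states stay distinguishable after centering;
  `simulate_state_patterns()` then emits positively scaled noisy copies
  of the rows as patterns whose source state matching should recover.

What the fixture does **not** emulate: correlated neighbouring genes
sharing peaks (every gene is featurised independently, and windows are
disjoint by construction); mark–mark correlation structure (planted
enrichments are independent across marks given the class); chromosome
heterogeneity, mappability artefacts, and replicate-level noise in the
peak caller. Passing tests therefore demonstrate the correctness of the
machinery and the recoverability of planted structure, not the
REMC-scale predictive performance on real epigenomes, which requires the
real consolidated tracks.

## Problem sizes and tolerances

The test-suite and acceptance-script cohorts are sized to exercise every
code path at statistically meaningful scale: parameter recovery at
n = 5000 genes (checked within 3 standard errors of the planted truth),
the repeated-split experiment at n = 900–2000 with k = 10 splits,
featurisation oracle equivalence on 100 random mini-genomes (up to 50
genes, 200 peaks; exact equality), AUROC against the all-pairs
concordance oracle on 200 random instances (exact), pattern/probability
reconstruction to 1e−9 relative tolerance, and state matching of 500
noisy planted patterns at 95% required accuracy. Numerical comparisons in
tests otherwise use `testthat`'s default tolerances.

## Known limitations

- The classifier is linear in max-enrichment features; interactions
  between marks (e.g. bivalent promoters behaving differently from the
  sum of their parts) are visible only through the pattern display, not
  modelled.
- `valley_threshold()` assumes an (approximately) bimodal RPKM
  distribution on the log1p scale; heavy intermediate expression defeats
  it and triggers the median fallback.
- Wald p-values assume the unpenalised MLE; after a separation fallback
  the package refuses inference rather than reporting approximations.
- The shipped 15-state → 4-group mapping is a reconstruction of the
  conventional grouping of the REMC core-mark model's mnemonics and is
  deliberately user-overridable.
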