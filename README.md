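# markstate

Predicting binary gene transcriptional state (ON/OFF) from
histone-modification ChIP-seq **peak calls**, with a model simple enough
to read: logistic regression on per-gene, per-mark maximum peak
enrichment around the TSS, plus a principled interpretation layer that
decomposes every prediction into per-mark contributions and matches them
against ChromHMM-style chromatin states.

It is aimed at computational epigenomics work where the question is not
only *"is this gene on?"* but *"which marks made the model say so?"*.

## The method in brief

For gene *g* and histone mark *h*, the input-field is the window of
*l* = 10 kb centered on the TSS. Localising the mark's peak track onto
the field gives a vector **x**<sup>g,h</sup> ∈ ℝ₊<sup>l</sup> holding
each covering peak's signalValue (0 where uncovered), and the feature is

> φ<sup>g</sup><sub>h</sub> = max<sub>i</sub> x<sup>g,h</sup><sub>i</sub>

Stacking gives Φ ∈ ℝ₊<sup>n×m</sup> over the five core marks H3K4me3,
H3K4me1, H3K36me3, H3K9me3, H3K27me3. Expression *t<sub>g</sub>* (RPKM)
is binarised at the per-tissue median (*t<sub>g</sub>* ≤ t̄ → OFF); a
density-valley threshold is available as an alternative. A logistic
model P(ON) = σ(b + **w**·**φ**) is fitted on raw features on the
training third of the genes; the peak format per mark
(narrowPeak/broadPeak/gappedPeak) is selected on validation AUROC; test
AUROC/F1/AUPR are averaged over k = 10 random splits.

For interpretation, each gene's *regulative pattern* is
**ψ** = **φ** ⊙ **w**, so the logit decomposes exactly as
y = b + Σᵢψᵢ: positive components are activating contributions, negative
repressive, and marks failing a Wald z-test at α = 10⁻⁴ are masked.
Patterns are matched to the chromatin state whose emission vector
maximises Pearson correlation (centered cosine), and states/state-groups
are ranked by the mean logit of their matched genes.

## Worked example

```r
library(markstate)

fx  <- generate_fixture(fixture_spec(n_genes = 1000, seed = 42))
phi <- build_feature_matrix(fx$genes, lapply(fx$tracks, `[[`, "narrow"))
labels <- binarise(fx$expression, median_threshold(fx$expression),
                   rule = "median")

feature_sets <- lapply(colnames(phi), function(h) list(narrow = phi[, h]))
names(feature_sets) <- colnames(phi)
run_experiment(feature_sets, labels, k = 10, seed = 7)
#> repeated-split evaluation: 10 splits (master seed 7 )
#>   AUROC mean 0.9292  sd 0.0100
#>   F1    mean 0.8533  sd 0.0149
#>   AUPR  mean 0.9207  sd 0.0097
```

The planted activator/repressor structure is recovered with the correct
signs, and every mark is significant on this cohort:

```r
fit <- fit_logistic(phi, labels)
fit
#> logistic gene-state model over 5 marks
#>   bias b = -1.4637
#>                w     se        z p
#> H3K4me3   0.8704 0.0693  12.5537 0
#> H3K4me1   0.5202 0.0539   9.6498 0
#> H3K36me3  0.6414 0.0593  10.8079 0
#> H3K9me3  -0.5409 0.0557  -9.7176 0
#> H3K27me3 -0.9027 0.0710 -12.7098 0
```

The negative bias acts as an activation threshold: a gene with no
measured epigenetic activity defaults to OFF. A single gene's prediction
decomposes into mark contributions (here display-normalised so the
tallest bar is ±1; `plot()` renders the usual green/red/grey bars):

```r
p <- compute_pattern(phi["g00004", ], fit, gene_id = "g00004")
normalise_for_display(p)
#> regulative pattern for g00004 (display-normalised)
#>              psi
#> H3K4me3   0.8961
#> H3K4me1   0.2672
#> H3K36me3  1.0000
#> H3K9me3  -0.5770
#> H3K27me3  0.0000
#> bias -0.5262  logit 1.0601
```

This gene is predicted ON (logit > 0): strong promoter (H3K4me3) and
structural (H3K36me3) enrichment outweigh the H3K9me3 contribution and
the negative bias; H3K27me3 called no peak in its promoter window.

Downstream, `compute_patterns()` + `match_states()` +
`gather_and_rank()` rank chromatin states (or 4 semantic groups, see
`default_state_groups()`) by the mean predicted-activation logit of
their matched genes.

A thin command-line front end over the same functions lives in
`inst/scripts/markstate.R` (subcommands `make-fixture`, `featurise`,
`fit`, `explain`, `match`).

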