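---
title: "Predicting cold-responsive differential expression from regulatory sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cold-responsive differential expression from regulatory sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degcnn)
```

## The question

When a plant is moved to the cold, some genes respond (up- or down-regulated
DEGs) and most do not (non-DEGs), and which genes respond varies among natural
genotypes. If cis-regulation drives part of this response, the DNA immediately
around a gene — its promoter and terminator neighbourhood — should carry
predictive signal. `degcnn` implements a pipeline that asks exactly this on a
panel of accessions: screen regulatory windows for enriched short motifs,
fit a random-forest baseline on known transcription-factor binding-site (TFBS)
counts, and train convolutional neural networks (CNNs) directly on one-hot
encoded windows to classify DEG vs non-DEG, with a positive-control "spike"
that bounds what the architecture can learn at all.

Because the real expression calls and pseudogenomes are an external resource,
the package ships a synthetic-data generator that reproduces the *statistical
structure* of such a study, so the entire pipeline is testable end to end.

## The label model in the generator

For gene $g$ with planted-motif occurrence counts $c_{gm}$ in one accession's
sequence,

$$P(\text{up}_g) = \operatorname{logit}^{-1}\!\Big(\beta_0 + \sum_m \beta_m\, c_{gm}\Big),$$

and a gene not drawn "up" is drawn "down" with the baseline probability
$\operatorname{logit}^{-1}(\beta_0)$. The default intercept is
$\beta_0 = \operatorname{logit}\big(r/(1+r)\big)$ with target ratio $r = 1/11$,
so with zero motif effects both DEG classes sit at the study's roughly 1:11
DEG:non-DEG imbalance. Counts are re-scanned per accession *after*
substitutions are applied, so a SNP that destroys a motif occurrence changes
that genotype's label probabilities — sequence and status co-vary across
genotypes, which is the genotype-by-environment structure the analysis is
meant to probe.

Choices the generator makes where the study design is silent:

* **Background composition** is i.i.d. uniform over ACGT (configurable GC).
  Nothing downstream assumes composition; the motif screen tests enrichment
  against a control set drawn from the same background.
* **Divergence between accessions** defaults to `snp_rate = 0.005`
  substitutions per bp. This is a placeholder magnitude for "closely related
  genotypes", not an estimate of any panel's diversity; no indels or
  rearrangements are simulated, so coordinates stay shared across accessions
  exactly as in a pseudogenome panel.
* **Families** are contiguous blocks of gene indices by default (a `shuffled`
  mode exists to stress the splitter). Family structure only matters to the
  splitter, not to the generator's sequences.
* **Gene placement** reserves the maximal window span (2 kb on either side)
  per gene, so no window is truncated and no two genes' windows overlap.
  Edge effects are still exercised in tests through hand-built fixtures.

What the generator does *not* emulate: linkage and coalescent structure,
realistic promoter composition, chromatin state, or any trans-acting
regulation. A model that performs well here has been shown to recover planted
cis signal through the whole pipeline — not to work on real genomes.

## Windows and encoding

All windows are defined in the gene's 5'→3' orientation; anchors are the
annotated gene start (taken as the TSS) and gene end (TTS). A convention
$(u, d)$ spans offsets $-u \dots d-1$ around the anchor, so the anchor base is
the first "downstream" base; minus-strand windows are reverse-complemented so
upstream is always leftmost. The conventions are 500+500 around TSS and TTS
for the motif screen, 1000+500 (TSS) concatenated with 500+1000 (TTS) for the
CNN input (L = 3000), and 2000+0 for the upstream-only variant (L = 2000).
Overhang beyond a chromosome end is filled with `N`, which one-hot encodes to
an all-zero row; internally coordinates are handled 0-based half-open and all
readers/writers speak 1-based inclusive GFF3.

## Splitting, oversampling, spike

Genes in one family share sequence by descent, so the train/validation/test
split assigns *whole families*: shuffle the family list, accumulate families
until the target record fraction is reached (test first, then validation from
the remainder). Fractions are honoured at family granularity, i.e. within a
few percentage points. The minority (DEG) class is then oversampled with
replacement to 1:1 — in the training set only; validation and test keep the
original ratio, and the validation split is carved *before* oversampling so
duplicated records can never straddle the boundary.

`inject_spike()` overwrites the first 5 bp of the upstream window of every
positive record with `AAGGG`. That makes class membership a deterministic
function of sequence, so any failure to reach high test prAUC on spiked data
is attributable to the architecture or the optimisation, not to the data.

## The motif screen

`discover_motifs()` is a deliberately small stand-in for a full de novo motif
finder, keeping its operating contract: enrichment of ungapped motifs in DEG
windows against a down-sampled non-DEG control, an e-value stop rule, and
both-strand matching. It scans every k-mer (k = 5..12) present in either set,
computes the one-sided Fisher p-value of its presence/absence 2×2 table
(equivalently the hypergeometric upper tail), and multiplies the best
candidate's p by the number of candidates evaluated in that round to get an
e-value. Accepted motifs are masked out and the scan repeats; candidates
within Hamming distance 1 of an accepted motif are treated as the same motif.
A round that accepts nothing changes nothing, so the "three consecutive
failures" stop rule fires deterministically at the first failed round.
Position-weight-matrix refinement, Markov backgrounds and gapped motifs are
out of scope; consensus exact matching is the match operation throughout.
`match_to_library()` compares a discovered motif to a PFM library by the mean
per-column Pearson correlation over all alignments with at least 5
overlapping columns (both orientations), with a column-shuffling null for the
p-value; zero-variance (uniform) columns contribute zero correlation by
definition, which makes an uninformative query unmatchable.

## The random-forest baseline

The baseline asks whether *known* TFBS counts (412 motifs + a total column =
413 features, counted in the 1 kb upstream window) predict DEG status.
The forest itself is `ranger` — 500 trees, `mtry = 200`,
impurity-corrected importance — because an off-the-shelf ensemble is part of
the design being reproduced; the package's own content is the feature
construction, the Altmann permutation p-values (via
`ranger::importance_pvalues`), and the prAUC significance: the label vector
is permuted and the forest refit 100 times, and the p-value is the fraction
of permuted out-of-bag prAUCs at least as large as the observed one.
Out-of-bag probabilities feed the prAUC; this is a documented choice (the
alternative, a held-out split, is available by splitting upstream of the
call).

## The CNN

No deep-learning framework is involved: the network is a compact engine
written for this package. Architecture, per grid point: one to three blocks
of `conv(filters, width) → ReLU → max-pool(pool_width, pool_stride)`, a
flatten, one or two hidden dense layers with ReLU and dropout, and a 1-unit
sigmoid output trained with binary cross-entropy and Adam (default learning
rate 0.0001, 50 epochs, minibatch 64, with a two-epoch linear learning-rate
warm-up: Adam's early normalised steps are as large as the target rate
regardless of gradient scale and can permanently silence rectified units when
the rate is aggressive relative to the initialisation). Hidden activations
are rectifiers and the optimiser is adaptive-moment gradient descent —
standard choices for this architecture family. Following the convention of the grid-summary tables,
the *number of dense layers includes the output layer*: `dense_units =
c(64, 128)` is a three-dense-layer model.

Implementation notes that matter for correctness and speed:

* Each conv→ReLU→pool block runs as one fused compiled kernel
  (`src/kernels.cpp`). Since ReLU is monotone, `max(relu(z)) = relu(max(z))`,
  so the kernel pools raw convolution scores and rectifies the pooled
  maximum; the full convolution map never materialises. The backward pass
  routes gradient only through each pooling window's argmax and only where
  the pooled activation is positive. Gradients were verified against central
  finite differences to ~1e-8 relative error (see the engine tests).
* Labels are DEG = 0, non-DEG = 1 and the sigmoid predicts the probability
  of label 1; prAUC uses the DEG class as positive by default (scores are
  `1 - p`). Both polarities are reported in `evaluate()` because the positive
  class of a precision-recall curve is a reporting convention, not a model
  property.
* After every epoch the validation prAUC is computed and the weights of the
  best epoch are the ones kept ("validation-prAUC model saving"); all
  reported metrics describe the saved model. Training prAUC is computed on
  the oversampled training set — the data the optimiser saw.
* Within-class accuracy thresholds the sigmoid at 0.5; `class_diff` is the
  absolute difference of the two within-class accuracies; a model with test
  prAUC above 0.8 or below 0.2 is flagged overfit-to-one-class.

`grid_search()` trains one model per hyperparameter combination, with every
combination using the same seed (identical combinations therefore give
identical metrics) and per-combination JSON checkpointing so a long search is
resumable. `select_best()` keeps records with test prAUC ≥ 0.7 and returns
the one with smallest class difference, ties broken by higher prAUC then grid
order. `permutation_significance()` re-trains the selected architecture with
training+validation labels jointly shuffled (test labels untouched,
training re-oversampled per shuffle) and reports the fraction of permuted
runs that are at least as good on *both* criteria (prAUC and class
difference).

The default grid (`hyper_grid()`) is a reduced Cartesian product over the
values observed in the best-model table: filters {64, 128}, conv width
{4, 8}, pool width {4, 8}, pool stride {4, 8}, dropout {0.1, 0.25}, dense
units {64, 128}, 1–3 conv layers, 1–2 hidden dense layers. The original
screen's full 1344-point grid is not published as data; the grid here is a
configuration artifact and any list of `hyperparams()` can be searched.

## Comparative statistics

`compare_distributions()` is a two-sample Kolmogorov–Smirnov test on a chosen
metric of two grid runs. `fit_effect_model()` fits the two mixed-effects
formulas used to summarise hyperparameter influence —
`class_diff ~ cl*dl + pl + du + (1|fl)` with Gamma errors (log link; a
class difference of exactly 0 is nudged to half the smallest positive value,
and flagged, because the Gamma family needs a positive response) and
`prauc_test ~ cl*dl*pl + dr + (1|fl)` with binomial errors as specified,
plus a beta-family alternative via `glmmTMB` because a binomial family for a
continuous proportion is unusual; both are labelled in the output. When the
random effect is inestimable the function falls back to a fixed-effects GLM
and says so. p-values come from a type-II analysis of deviance
(`car::Anova`). `rank_sum_motif_comparison()` is the two-sided Wilcoxon
rank-sum test of per-gene discovered-motif counts split by prediction
correctness.

## Problem sizes used in the shipped tests

The test-suite experiments are scaled to a single CPU: the spike-learnability
study uses ~2,000 records (440 genes × 5 accessions at 1:11 imbalance,
upstream-only windows) and a 16-filter single-conv-layer model trained for
20 epochs at learning rate 0.001 (minibatch 32), run paired — spiked vs
plain data, same weights initialisation — over 5 seeds; motif recovery uses
300 windows per class of 150 bp over 20 seeds; the permutation-significance
check uses 20 permutations of a small model on short separable windows. These sizes are the package's chosen study
conditions for its synthetic benchmarks; the interfaces accept the full-size
settings (50 epochs, L = 3000, 100 permutations) unchanged.

## Known limitations

* The motif screen reports exact-consensus motifs, not refined PWMs; its
  counts are comparable across genes but not across motif finders.
* The CNN engine is single-threaded CPU code. It is adequate for grids of
  small models on desk-scale data; it is not a route to the full-size screen.
* Gamma/binomial choices for the effect models follow the design being
  reproduced; for publication-grade inference on grid summaries the beta
  family is the defensible default, which is why it ships alongside.
* With heavy class imbalance, thresholded within-class accuracies are noisy
  even when ranking (prAUC) is good; `class_diff` near 1 with high prAUC
  usually means the decision threshold, not the representation, is the
  limiting factor.
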