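---
title: "Weighted kernel fusion for protein subcellular localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted kernel fusion for protein subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goTLM)
options(goTLM.verbose = FALSE)
```

## The problem and the model

Predicting the subcellular compartment a protein resides in from its
sequence alone is hard; gene-ontology (GO) annotations transferred from
homologous or signature-matched proteins carry much stronger signal,
but the three GO aspects — biological process (P), molecular function
(F), cellular component (C) — differ widely in how informative and how
complete they are, and transferred terms can be wrong when homologs
have diverged.  goTLM treats each information source as its own
similarity channel and lets the data decide how much each contributes.

Five feature channels are built per protein:

* **AA** — amino-acid composition: relative frequency of the 20
  standard residues (fixed order `ACDEFGHIKLMNPQRSTVWY`).
* **diAA** — di-peptide composition: frequencies of the 400 ordered
  residue pairs over a sliding window of width 2.
* **P**, **F**, **C** — binary indicator vectors over the sorted GO
  vocabulary of each aspect, frozen from the training set.

Each channel $e$ is turned into a Gaussian kernel

$$K_e(x, y) = \exp\!\left(-\gamma\,\lVert x - y\rVert^2\right),$$

with one $\gamma$ shared across channels, and the channels are fused by
a convex combination

$$K = \sum_{e \in \{P,F,C,AA,diAA\}} w_e\,K_e,
\qquad w_e \ge 0,\ \sum_e w_e = 1,$$

which is again a valid (symmetric, positive semi-definite) kernel.  A
one-vs-one multiclass C-SVM is trained on the fused kernel.

## Non-parametric channel weighting

Rather than optimizing the $w_e$ by semi-definite or semi-infinite
programming, each channel is scored *on its own*: a single-channel SVM
is cross-validated over `cvK` folds of the training partition, the test
folds are pooled into one confusion matrix $M$, and the channel is
summarized by its overall sensitivity and the aggregate multiclass
Matthews correlation coefficient.  With $p_l = M_{l,l}$,
$q_l = \sum_{i \ne l}\sum_{j \ne l} M_{i,j}$,
$r_l = \sum_{i \ne l} M_{i,l}$, $s_l = \sum_{j \ne l} M_{l,j}$ and
$p, q, r, s$ their sums over classes,

$$\mathrm{SE} = \frac{\sum_l M_{l,l}}{\sum_{i,j} M_{i,j}}, \qquad
\mathrm{MCC} = \frac{pq - rs}
{\sqrt{(p+r)(p+s)(q+r)(q+s)}},$$

and the weights are the normalized products

$$w_e = \frac{\mathrm{SE}_e \cdot \mathrm{MCC}_e}
{\sum_c \mathrm{SE}_c \cdot \mathrm{MCC}_c}.$$

SE alone favours the predominant class on unbalanced data; multiplying
by MCC penalizes exactly that bias, so a channel that merely predicts
the majority class scores near zero.  Negative products (a
worse-than-random channel) are clamped to zero before normalization: a
negative weight would break positive semi-definiteness of the fusion,
and a harmful channel should contribute nothing.  If *every* product is
zero the weights fall back to uniform with a warning — this happens on
label-randomized data and is the honest answer there.

Two details are worth flagging:

* **SE is the overall (pooled) form**, identical to overall accuracy,
  not a macro-averaged recall.
* **The aggregate MCC denominator factors $p+r$ and $p+s$ always equal
  the total count**, so the zero-denominator convention (return 0) can
  only trigger on degenerate matrices; it is retained for safety and
  for the per-class MCC, where it genuinely occurs.

Per-class tables report SP, SE and MCC per location.  Per-class SP is
implemented as precision $p_l/(p_l + r_l)$ — the dominant convention in
the subcellular-localization literature — and per-class SE as recall
$p_l/(p_l + s_l)$; where a denominator is zero the value is reported as
0 and flagged in the `spDefined`/`seDefined` columns.

## Training protocol

`trainGoTlm()` grid-searches three hyper-parameters:

| parameter | grid | meaning |
|---|---|---|
| `cvK` | {3, 5, 10} | inner folds for weight estimation and internal model scoring |
| `gamma` | {2⁻¹, 2⁻², 2⁻³, 2⁻⁴} | Gaussian width, shared by all channels |
| `C` | {2¹, …, 2¹¹} | SVM cost |

For each combination the weights are re-estimated on the training
partition, the fused-kernel SVM is scored by internal `cvK`-fold CV
overall accuracy, and the best combination wins.  Ties break toward the
smallest `C`, then the largest `gamma`, then the smallest `cvK` —
preferring the smoother, less complex model.  Fold splits follow the
equal-size rule: a seeded random permutation cut into `K` contiguous
blocks, the first `K − 1` of size `⌊n/K⌋` and the last taking the
remainder, without stratification.  `crossValidate()` wraps the whole
procedure (vocabularies, weights, grid search) inside each outer
training partition, so nothing about a held-out fold — not even its GO
vocabulary — influences the model that predicts it.  Weight estimation
is nested inside every outer fold rather than reusing one weight vector
per dataset; this is the leak-free reading of the protocol, and the
per-fold weight vectors the report returns let users check how stable
the estimates are.

Single-channel scoring reuses the candidate $(\gamma, C)$ of the grid
point under evaluation rather than running a second nested grid; this
keeps cost linear in the number of channels.

## Numerical and implementation choices

* **Gaussian exponent sign.** The kernel is computed with the standard
  negative exponent; a positive exponent grows without bound and is not
  a valid kernel.
* **Frequencies, not counts.** Compositions are relative frequencies,
  so the kernel length-scale does not depend on sequence length.
  Ambiguity letters (B, Z, X, U, O, J) are excluded from numerator and
  denominator rather than remapped.
* **Empty vocabularies.** A channel whose vocabulary is empty yields
  the all-ones kernel — uninformative, so its SE·MCC weight collapses —
  rather than an error; datasets missing a whole aspect still train.
* **Out-of-vocabulary terms** on test proteins are dropped and counted
  (never retrained into the model); a test protein with no in-vocabulary
  terms is classified from its remaining channels.
* **SVM solver.** Each square kernel is factored through its
  eigendecomposition, $K = \Phi\Phi^\top$ with
  $\Phi = V D^{1/2}$ (eigenvalues below $10^{-10}$ of the largest are
  treated as numerical zeros), and the binary one-vs-one subproblems
  are solved by libsvm with a linear kernel on the rows of $\Phi$ —
  the decision functions are identical to training on $K$ directly,
  and new proteins map in via $\Phi_{\mathrm{test}} = K_{\mathrm{test}}
  V D^{-1/2}$.  The voting layer is in-package so the tie rule is
  explicit: vote ties go to the class earlier in the stored (sorted)
  class order.  Tests cross-check the decisions against an independent
  precomputed-kernel SVM implementation (kernlab).
* **Determinism.** Every random step (fold splits, data generation)
  derives from a single integer seed; identical seed and configuration
  reproduce reports and prediction files bit-for-bit.
* **Masking channels** (`modelConfig(channels = ...)`) is implemented
  as — and tested to be — equivalent to forcing the masked weights to
  zero and renormalizing over the rest, which is how component-channel
  ablation experiments are expressed.

## What the synthetic generator emulates

`generateDataset()` produces FASTA + annotation + label triples with
the structure the model assumes:

* **Location-dependent composition**: each class draws a residue
  distribution from a symmetric Dirichlet; the concentration parameter
  (default 100) keeps the sequence signal weak relative to GO, matching
  the observation on real benchmarks that GO features dominate
  sequence features.
* **Location-informative GO terms**: each class owns a disjoint pool of
  `poolSize` (default 10) terms per aspect; a protein emits
  Binomial(`poolSize`, informativeness) of its own pool's terms.
  Default informativeness C = 0.70 > P = 0.35 > F = 0.18 encodes the
  component-strongest regime.
* **Missing annotation**: with probability `missingRate` per aspect a
  protein has no terms of that aspect at all.  The defaults
  (P = 11.7 %, F = 13.4 %, C = 0.6 %) reproduce the per-aspect missing
  rates reported for a large curated eukaryotic benchmark, where the
  component aspect is nearly complete.
* **Annotation noise**: Binomial(`poolSize`, `noiseRate`) terms from
  *other* classes' pools emulate erroneous homology transfer.

Four frozen presets cover the regimes of interest: `separable`
(defaults; 5 classes × 50), `noisy`, `low-coverage`, and `null`
(labels permuted after generation — chance-level by construction;
3 classes × 100).

What the generator deliberately does **not** emulate: real GO DAG
structure (terms are flat tokens, no ancestor propagation — consistent
with treating transferred terms as a flat binary vector), shared terms
between locations, realistic sequence evolution, or multi-location
proteins.  Passing tests on these data therefore demonstrate that the
machinery — feature construction, weighting, fusion, protocol — behaves
as specified, not that any particular accuracy will transfer to real
proteomes.

## Problem sizes and runtime

The shipped evaluation runs use the presets above (n = 250 and n = 300)
with the single grid point `cvK = 5`, `gamma = 2^-2`, `C = 2^7` — the
combination the full grids select on well-annotated data — which keeps
a full nested 5-fold cross-validation to well under a minute.  The full
132-point grid is the default for real analyses and costs roughly the
grid size times one weight estimation per outer fold.

## Known limitations

* Single-label prediction only; multi-location proteins are out of
  scope.
* No probability calibration; the per-protein decision summary is the
  one-vs-one vote count and margin.
* GO terms are treated as flat tokens; annotating with very specific
  terms unseen in training reduces to the sequence channels (the
  dropped-term count in the log flags this).
* A single shared `gamma` across channels trades per-channel
  adaptivity for a small, well-behaved grid.
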