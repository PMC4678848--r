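---
title: "Predicting DNA-binding proteins from amino acid composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding proteins from amino acid composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantDBP)
```

## Overview

plantDBP builds lineage-specific classifiers of DNA-binding proteins
(DNA-BPs) from amino acid composition alone. This vignette explains the
statistical model, the data-curation pipeline around it, the parameters
that matter, the synthetic-data generator used for testing, and the design
choices made where more than one defensible option existed.

## Why composition, and why lineage-specific models

Many DNA-BP families — plant transcription-factor families in particular —
are lineage-specific, so classifiers trained on mixed prokaryote/eukaryote
sets or on structure-restricted sets under-represent exactly the proteins
a plant annotator needs. Evolutionary-profile features (PSSMs) are also
unavailable for species with few sequenced relatives. Amino acid
composition is the simplest informative feature: protein–DNA interfaces
are enriched for positively charged residues, and a 20-dimensional
composition vector is computable for any sequence, at proteome scale, in
seconds. The cost of this simplicity is a known failure mode: RNA-binding
proteins and some zinc-finger proteins share the compositional signature
and are predicted as DNA-binding; the annotation-comparison machinery
(below) exists to make that visible rather than hidden.

## Training-set curation

**Sequence validation.** FASTA input is uppercased, terminal stop
characters are stripped, duplicate identifiers and invalid residue
characters are hard errors naming the record (and position). The tolerated
noncanonical codes are X, B, Z, J, U, O — selenocysteine and pyrrolysine
are accepted at read time because source proteomes contain them, but they
carry no composition information here (see below). Proteins shorter than
40 residues are removed as presumptive fragments.

**GO selection.** Positives are proteins with at least one
molecular-function annotation, under an allowed evidence code, inside the
`is_a` descendant closure of the DNA-binding roots GO:0003677 and
GO:0003700. Negatives are proteins with at least one allowed
molecular-function annotation, none of which is in the closure. Two
policies are provided: `experimental_direct` (IDA only) for well-annotated
model species, and `manual` (EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC) when
direct-assay evidence alone is too scarce; the `manual` set is this
package's operating definition of "manually curated" and is exposed as
configuration rather than hard-coded. Only `is_a` edges are used for the
closure: the molecular-function hierarchy is essentially `is_a`, and
adding `part_of` would change class membership silently. A protein
carrying both a DNA-binding and a non-DNA-binding annotation is excluded
from the negative class — it is positive evidence, not an absence of it —
which avoids label noise at the cost of a slightly smaller negative pool.

**Homology reduction.** Redundant sequences inflate cross-validation
estimates. Sequences are clustered by single linkage over edges defined by
a local alignment (BLOSUM62, affine gaps 11/1) reaching ≥ 35 % identity
over ≥ 90 % of *both* sequences, and one representative per cluster is
drawn uniformly under the seed. The both-sequence coverage rule is
deliberately conservative: a domain shared between a short and a long
protein then counts as homology only if it spans both, which errs toward
removing potential train/test leakage. The identity/coverage semantics of
the classic clustering tools are not exactly re-derivable from their
documentation; these definitions are this package's own, fixed, documented
operating point. Percent identity is identical columns over alignment
columns. When several local alignments are co-optimal the implementation
reports one of them; the test suite checks it against the full co-optimal
set enumerated by an independent dynamic-programming oracle.

**Dataset assembly.** Balanced splits sample exact class counts without
replacement under one seed and guarantee train/test disjointness.
Realistic splits model the ~10:1 excess of non-DNA-BPs in a proteome: the
negative pool is halved (training receives the larger half when odd) and
each side receives `floor(negatives/ratio)` positives. With the reference
pool of 1767 negatives this yields 884/883 negatives and 88 positives per
side. Cross-set homolog exclusion removes candidates aligning above the
thresholds to any reference-set protein, so an independent test pool stays
independent of the training species.

## The classifier

**Features.** The 20 canonical residue fractions, in fixed alphabetical
order (A, C, D, …, Y). Noncanonical residues are excluded from both the
numerator and the denominator, so vectors always sum to one; a sequence
with more than 10 % noncanonical residues is rejected (the tolerance is a
parameter — the default guards against junk records without discarding
proteomes containing occasional selenoproteins). The feature order is
written into every model file; loading a model with a permuted order is an
error, not a silent permutation. Fractions are already in [0, 1] and are
used raw — no standardisation is applied, and this is recorded in the
model file rather than left implicit.

**SVM and grid search.** A C-classification SVM with RBF kernel (libSVM,
via e1071). Cost and γ are selected over the standard practitioner grid
(`C = 2^-5 … 2^15`, `γ = 2^-15 … 2^3`, step ×4) by stratified
`inner_folds = 5` cross-validation on the training data, maximising
accuracy. Ties are broken toward smaller cost, then smaller γ — the
smoother model. With a strongly separable training set many grid points
tie at the maximum, and the tie-break then selects a flat model whose
decision values are numerically tiny; the calibration step below is
written to survive that.

**Probability calibration.** libSVM's own `-b 1` probability machinery is
not seedable from R and produces run-to-run differences. The package
therefore implements the same procedure under its own seed: decision
values are produced by stratified k-fold cross-validation within the
training set, and a Platt sigmoid `P(DNA-BP | f) = 1/(1 + exp(A f + B))`
is fitted by penalised maximum likelihood with Newton steps and
backtracking line search, using the standard shrunk targets
`(N⁺+1)/(N⁺+2)` and `1/(N⁻+2)`. The decision values are scale-normalised
before the fit and the slope rescaled afterwards — an exact
reparameterisation that keeps the Newton iteration well-conditioned when
the selected model's decision values are far from unit scale. The
resulting pipeline is bit-reproducible: the same seed gives byte-identical
model files and prediction tables.

**Prediction records.** Each protein receives `p_dna_bp` (calibrated
posterior of the DNA-BP class) and `probability_score = max(p, 1−p)`, the
posterior of the predicted class, bounded in [0.5, 1]. Thresholds for
proteome-scale annotation are applied to the probability score,
inclusively (≥), matching how the ≥ 0.85 operating point is stated.

## Evaluation

Cross-validation is stratified 5-fold; each training fold runs its own
grid search. The summary confusion matrix is pooled over folds rather than
averaging per-fold metrics: with 100-protein folds a single misclassified
protein moves a per-fold metric by a full percentage point, and pooling is
the stabler summary; per-fold reports are returned alongside. Metrics with
zero denominators are reported as `NA` rather than zero. All computation
is at full precision; the 2-decimal rounding seen in report tables is
display-layer only.

**Threshold selection.** DNA-BPs are expected to form roughly 6–7 % of a
eukaryotic proteome. `select_threshold()` computes
`round(expected_fraction × proteome_size)` (half-up, so 0.06 × 34725 →
2084) and returns the smallest threshold in the sweep whose predicted-set
size does not exceed that expectation — the largest credible predicted
set. On the published tomato sweep (2438 / 1459 / 659 predictions at
0.80 / 0.85 / 0.90) this selects 0.85. If every row exceeds the
expectation the largest threshold is returned with a warning rather than
an error, since a user may legitimately sweep a narrow range.

## Proteome-scale annotation

**Annotation classes.** Predicted DNA-BPs are compared against existing
annotation: `GOA_DB` (a GO term in the DNA-binding closure, or a domain
description matching a DNA-binding keyword list), `GOA_UNKNOWN` (no GO
term and no domain), `GOA_OTHER` (annotated, other functions). The domain
keyword list ("DNA-binding", "transcription factor", "histone",
"helix-turn-helix", zinc-finger-with-DNA patterns) is explicitly a
configurable operating definition — domain-to-function judgments made by
human curators cannot be reconstructed exactly, and the package does not
pretend to.

**Enrichment.** Nuclear-localisation enrichment is the plain ratio of
proportions `(nNL_DBP / nDBP) / (nNL_prot / nProt)`, consuming rank-1
flags from a subcellular-localisation ranking table. GO term enrichment is
a one-sided Fisher's exact test per study-set term (over-representation,
as singular enrichment analysis tools perform it) with Benjamini–Hochberg
FDR; proteins without GO terms are removed from both sides first, and
study proteins are excluded from the comparison side so the 2×2 table
contrasts the study set with the rest of the reference.

## The synthetic generator

The generator emulates the one property of real data the classifier can
see: a compositional difference between classes. Sequences are drawn
i.i.d. per residue; the positive class adds `effect_delta` total
probability mass (default 0.08) split across `effect_residues` (default K
and R), with the other residues scaled down proportionally, so the
K+R-fraction gap between classes is exactly the nominal δ in expectation.
The default base composition is uniform (0.05 per residue) so tests are
self-contained rather than tied to an external composition table; lengths
are uniform on 100–500 residues, a realistic span for full-length
proteins and safely above the 40-residue filter. Optional homolog families
are seeded point mutants of a parent at fewer than 10 % of positions
(hard-capped), guaranteeing within-family identity above 90 % so homology
reduction provably recovers the families.

What the generator does *not* emulate: motif structure, domain
architecture, length–class correlations, phylogenetic correlation between
sequences, or annotation errors. A pass on synthetic data therefore
demonstrates that the machinery recovers a known compositional signal at
realistic sample sizes — not that real proteomes will be predicted with
the same accuracy.

Problem sizes used by the test suite and the acceptance script were chosen
to finish in minutes on one CPU while keeping the statistical checks
meaningful: separable recovery at n = 200/200 with δ = 0.08 (full default
grid, pooled 5-fold CV accuracy ≥ 0.90), a null configuration at
n = 250/250 with δ = 0 (|MCC| ≤ 0.15), and a 50-replicate exchangeability
check of the generator at n = 500/500.

## Numerical and degenerate-input choices

* Empty FASTA input is a warning with an empty record set; downstream
  operations decide whether emptiness is fatal.
* All-noncanonical sequences, single-class training sets, non-finite
  features, all-zero confusion matrices, and requests exceeding pool sizes
  are errors naming the offending record or count.
* Grid ties: smaller cost, then smaller γ. Platt iteration: at most 100
  Newton steps, gradient tolerance 1e-5, minimum line-search step 1e-10.
* Cluster ids are assigned in input order of first membership and
  representative sampling is seeded, so reruns are reproducible and
  changing the seed can change representatives but never membership.
* Sampling uses one seeded generator per operation (`balanced_split`,
  `homology_reduce`, …) via a local-seed wrapper that restores the
  caller's RNG state, so library calls do not perturb user scripts.

## Known limitations

* Composition-only features cannot distinguish DNA-binding from
  RNA-binding or some protein-binding zinc-finger proteins; expect
  `GOA_OTHER` predictions enriched for those classes.
* The homology engine is exact pairwise alignment over all pairs —
  appropriate for curated training pools (hundreds to a few thousand
  sequences), not for clustering whole proteomes; no k-mer prefilter is
  provided.
* Evidence-code presets reflect this package's definitions; users
  replicating a specific external curation should pass their exact code
  set.
* The published proteome-scale figures (e.g. the tomato prediction counts)
  depend on the original supplementary datasets; without them the package
  reproduces the printed worked examples and the full pipeline on
  synthetic data, and accepts the original datasets as optional inputs
  when available.
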