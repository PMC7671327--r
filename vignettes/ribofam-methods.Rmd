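---
title: "Methods: ribosomal protein families, conservation, and cross-species tissue signal"
author: "ribofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ribosomal protein families, conservation, and cross-species tissue signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofam)
```

## The scientific problem

Ribosomal proteins (RPs) — roughly 80 core genes plus a handful of
paralogs in vertebrates — build one of the most conserved machines in the
cell, yet individual RPs differ considerably in how well their sequences
are conserved across the vertebrate lineage, and a few paralogs (RPL3L in
striated muscle; RPL10L, RPL39L, RPS4Y2 and RPL26L1 in testis) are
strongly tissue-restricted. ribofam implements a two-arm analysis of this
tension:

1. **Sequence arm.** Group a curated multi-species RP protein collection
   into families by masked all-vs-all local alignment, a percent-identity
   network and Markov clustering (MCL), then quantify each family's
   conservation by its best human–zebrafish pair and compare the small
   (SSU) and large (LSU) subunit groups.
2. **Expression arm.** Normalise cross-tissue expression (GTEx-style TPM,
   cRPKM for other vertebrates), summarise per-tissue RP expression,
   train nested cross-validated multiclass tissue classifiers, and ask —
   with an exact one-tailed binomial test — whether a classifier trained
   on human profiles predicts tissue identity in another species better
   than chance. If it does, tissue signal is conserved across species;
   if not, expression variation is species-dominated.

Every stage is exercised end to end on synthetic data with known ground
truth, generated by the package itself, so no external downloads are
needed to validate the machinery.

## Sequence arm

### Collection encoding

Records are encoded `<Gene>_<Species>_<role>_<n>` (e.g.
`RPL39L_Macaca_ref_0`): within each (gene, species) group the longest
sequence is the reference (`ref`, index 0) and the remaining isoforms are
`iso_1..k`, ordered by decreasing length. Length ties are broken by
lexicographically smaller source accession, then input order — the
encoding does not specify tie handling, so we chose the rule that makes
`mark_reference_isoforms()` deterministic and permutation-invariant.
Residues outside the 20-letter alphabet (B, Z, J, U, O, `*`) are
normalised to `X` because every downstream scoring step is defined on the
20+X alphabet.

### Low-complexity masking

Compositionally biased segments inflate local-alignment scores, so before
comparison each sequence is masked CAST-style: it is locally aligned
against an unbounded homopolymer of each residue type under BLOSUM62 with
a linear gap penalty (11 per skipped residue). Because a BLOSUM62 mismatch
always scores better than a deletion at that cost, the optimal local
segment is simply the maximum-sum subarray of the per-position scores
against that residue, found with Kadane's algorithm. While any
homopolymer score exceeds the threshold (default 40, the conventional
CAST cutoff), occurrences of the offending residue inside its optimal
segment become `X` and the search repeats; residue types are processed in
decreasing-score order with alphabetical tie-breaks, making the output
deterministic. Masking only ever substitutes towards `X`, so it can never
increase a pairwise alignment score (a property the test suite checks).

### Alignment and significance

Pairs are compared by exact Smith–Waterman with affine gaps (Gotoh
algorithm, implemented in C++), not by a seeded heuristic: at collection
scale (~10^3 sequences of 80–400 residues) exactness is affordable and
makes the aligner verifiable against an independent dynamic-programming
oracle, which the tests do on seeded random pairs. Defaults are BLOSUM62,
gap open 11, gap extend 1 (a gap of length L costs 11 + L), and gapped
Karlin–Altschul constants λ = 0.267, K = 0.041:

\[ \text{bits} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
   E = K \, m \, n \, e^{-\lambda S} . \]

Identity is computed over aligned columns of the masked sequences; `X`
participates in columns but never counts as a match, even opposite
another `X`.

**Search-space convention.** For a single pair (`local_align()`) the
search space is the pairwise product m·n. For `all_vs_all()` and the
six-frame rescue search, however, the search space is the query length
times the *total* length of the collection (respectively, of all
translated segments) — the convention BLAST and TBLASTN use for database
searches. The distinction matters: with a per-pair convention, an E < 0.05
cutoff budgets one chance hit per twenty *pairs*, so a 600-pair all-vs-all
admits tens of chance alignments, and short 16-column alignments at
exactly 50% identity occasionally attach unrelated sequences to family
clusters. The database convention budgets one chance hit per twenty
*searches*, which is both what the published comparisons effectively used
and what keeps random decoys unconnected. The collection itself defines
the database, so the statistic remains fully deterministic.

### Network and Markov clustering

Significant hits with identity ≥ 50% (the threshold that separates
ortholog families from spurious cross-family hits) become undirected
edges weighted by percent identity; sequences whose hits all fall below
the threshold remain as isolated nodes. MCL is implemented from scratch:

* self-loops are added with weight equal to the node's maximum incident
  edge weight (Biolayout-style; a loop of 1 would be negligible against
  identity-percent weights), or 1 for isolated nodes;
* columns are normalised to a stochastic matrix; then expansion (matrix
  squaring) alternates with inflation (entrywise power 1.8 followed by
  column renormalisation), pruning entries below 10⁻⁵, until the matrix
  changes by less than 10⁻⁶ or 200 iterations elapse (non-convergence —
  possible on adversarial symmetric graphs that oscillate — warns and
  interprets the current matrix);
* clusters are read off attractor rows (nodes with positive return
  probability); mutually attracting attractors merge into one attractor
  system, each cluster is a system plus the nodes it attracts, a node
  attracted by several systems joins the largest cluster (ties: lowest
  cluster id), and clusters below the minimum size (3) dissolve into the
  unassigned set.

On disjoint cliques this provably reduces to connected components for any
inflation > 1, which is the oracle the tests use; `binary_edges = TRUE` is
available because upstream tooling is ambiguous about weighted input.

### Conservation score and the subunit comparison

Each cluster's conservation is the highest alignment identity among its
(human, zebrafish) member pairs — the two best-curated, most distant
species in the set; clusters lacking either species are flagged rather
than scored. SSU/LSU labels derive from RP nomenclature (`RPS*`, `RPSA`,
`FAU` → SSU; `RPL*`, `RPLP*`, `UBA52` → LSU) with an explicit override
table, and the mixed fusion-precursor cluster (RPS27A with UBA52) is
excluded by listing both genes. The location shift between subunit groups
is tested with a two-sided Wilcoxon rank-sum test — exact when both
groups have ≤ 25 untied observations, normal approximation with tie
correction otherwise — and both median and mean differences are reported,
since "the shift" could reasonably denote either.

## Expression arm

Expression lives in a genes × samples matrix with a missing-value mask
and per-sample metadata (collection site, tissue category, species,
donor); GCT v1.2/1.3 and cRPKM-style TSV readers/writers are provided.
Min–Max scaling maps non-missing values to [0, 1] either per gene or per
organism (one mapping per species across all its cells); constant units
scale to all-0 rather than NaN so matrices stay dense for classifiers,
and missing cells are excluded from the min/max and stay missing. The
shipped 54-site → 33-category tissue mapping is a best-effort
reconstruction (the exact grouping is not published): cerebellum is kept
apart from other brain regions and the two cultured cell lines remain
their own categories, as the observed expression patterns require; the
YAML file is user-editable and `assign_tissue_categories()` refuses
unmapped sites rather than guessing. Six gender-associated paralogs
(RPL10L, RPS4X, RPS4Y1, RPS4Y2, RPL39L, RPL26L1) are removed before
classification, taking a GTEx-shaped 89-gene matrix to 83. t-SNE is
delegated to Rtsne (perplexity 30, 1000 iterations, fixed seed 0 by
default) and is plumbing, not methodology.

## Learning arm

Four model families are trained on scaled profiles: one-vs-rest logistic
regression, linear-kernel SVM, RBF-kernel SVM, and random forest. Library
mappings worth knowing:

* OVR logistic regression uses glmnet ridge per class with
  λ = 1/(C·n_train), so the C grid {0.01, 0.1, 1, 10, 100} has its usual
  inverse-regularisation meaning; prediction is argmax of the per-class
  linear scores.
* SVMs use e1071 (libsvm) with the same C grid; the RBF γ grid is
  {1/p, 0.01, 0.1}. libsvm's multiclass scheme is one-vs-one.
* randomForest exposes no depth parameter, so the forest grid is
  trees {100, 300} × mtry {√p, p/3}.

**Protocol.** The data are split three times into stratified 90/10
train/test partitions (outer loop); within each training set a stratified
5-fold grid search picks hyperparameters by accuracy (inner loop,
deterministic tie-break on grid order); the winner is refitted on the
full training set and evaluated on the held-out 10%. Min–Max scaling is
fitted on the training rows only and applied to the test rows — test
values may legitimately fall outside [0, 1], which is the observable
proof that no leakage occurred (asserted in the tests). Accuracy,
macro-averaged F1 (with support-weighted F1 alongside, since the
averaging scheme is often left unstated) and the multiclass Matthews
correlation coefficient (Gorodkin's R_K, equal to the Pearson correlation
of one-hot predictions and truth) are aggregated as mean ± sd over the
three splits. A fixed scheme seed makes the whole procedure
bit-reproducible.

**Cross-species transfer.** The classifier trains on one species
(human), restricted to the genes complete in the test species and to the
test set's tissue categories, and predicts the test species' tissues.
Here — deliberately, for fidelity to the published protocol — train and
test matrices are Min–Max scaled *independently* per gene, in contrast to
the leakage-safe within-species protocol; independent scaling is also
what removes the species-level offset and lets tissue signal transfer.
The tally of correct predictions is scored with the exact one-tailed
binomial test, `P(X ≥ k)` for `X ~ Binomial(n, p0)`; the chance level p0
defaults to 1/K over the K test tissues (a majority-class null is
available), because the original null is unstated. The model family
feeding the binomial test is likewise unstated and therefore an argument;
the package's own operating-characteristic runs use the linear SVM — see
the caveat below.

## Synthetic data: what it emulates, and what it does not

`simulate_families()` draws an ancestral sequence per family (length
uniform in 80–400, residues from BLOSUM62 background frequencies) and
diverges it independently into each species (star phylogeny) by i.i.d.
substitutions whose replacements follow off-diagonal BLOSUM62 exchange
propensities — keeping the identity/score relationship realistic — plus
rare short deletions; optional further-diverged paralogs and inserted
homopolymer runs exercise the paralog and masking paths, and decoys are
fresh random sequences. The default branch divergence 0.10 yields ~80%
within-family identity (well above the 50% network threshold); 0.125
yields the ~75% regime used in calibration tests. A star phylogeny cannot
produce the nested clade structure of real vertebrate evolution, and
i.i.d. substitution ignores site-rate variation; both are irrelevant to
what the tests assert (family recovery, threshold behaviour).

`simulate_expression()` works on the log scale:
log2(x+1) = μ_g + α_t + β_s + γ_gt + ε, with per-gene baselines
μ_g ~ N(6, 1) (a highly expressed gene class), scalar per-tissue effects
α_t shared across species, per-species offsets β_s, optional
per-(gene, tissue) enrichments γ for paralog-style tissue restriction,
and Gaussian noise; values return to a TPM-like scale and cells go
missing at a configurable rate (cRPKM-style). Three shipped scenarios fix
the regimes of interest: `tissue_dominant` (α sd 1.0, β sd 0.5, ε sd
0.25 — transfer should succeed), `species_dominant` (α ≡ 0, β sd 1.0 —
transfer should sit at chance) and `null` (no signal at all — classifier
calibration). What the generator does *not* emulate: gene–gene
correlation beyond the shared tissue/species factors, library-size
artefacts, and count noise; passing tests therefore demonstrate the
machinery's correctness under the stated model, not performance on real
GTEx-scale data.

Two statistical-design notes, both discovered during implementation and
kept as explicit choices:

* **Test-set size for the transfer scenarios.** With 2 test samples per
  tissue (n = 6, p0 = 1/3) the exact binomial null gives
  P(X ≥ 4) = 0.1001, so the modal above-chance outcome can never reject
  at the 0.1 threshold — a discreteness artefact. The scenarios therefore
  provide 4 test samples per tissue (n = 12), the smallest size at which
  the 0.1 level is attainable at realistic accuracy.
* **OVR and ordered classes.** Because the generator's tissue effect is a
  scalar, features are effectively one-dimensional and the *middle*
  tissue is not linearly separable one-vs-rest; OVR logistic regression
  systematically loses it while one-vs-one SVMs do not. The
  operating-characteristic runs therefore use the linear SVM; this is a
  property of OVR on ordered classes, not a defect of the generator.

## Numerical choices and degenerate inputs

* MCL: prune 10⁻⁵, convergence tolerance 10⁻⁶, max 200 iterations;
  cluster order (size desc, then first member id) and overlap resolution
  are deterministic.
* Masking: threshold 40, linear gap 11; a guard stops the loop if a
  biased segment carries none of the scored residue type.
* Min–Max: constant units → 0; empty/all-missing units untouched.
* Metrics: MCC is defined as 0 when its denominator vanishes (e.g. a
  single predicted class); per-class F1 is 0 when precision + recall = 0.
* `binomial_significance(0, n, p0)` = 1 exactly; p0 must lie strictly in
  (0, 1).
* Empty collections, empty hit lists and empty graphs all propagate as
  empty results rather than errors; empty *sequences* are errors.

## Problem sizes used by the tests

The suite and the acceptance script run entirely on synthetic data sized
for a laptop: 100 random 30-mer pairs for the aligner oracle; clique
graphs up to 30 nodes and 50 random graphs for MCL properties; 10 seeds
of the full sequence pipeline at 5 families × 6 species + 5 decoys
(~35 sequences, ~600 alignments per seed); 20 seeds of null-label
calibration and 50 seeds per transfer regime at 40 genes, 3 tissues,
30 + 12 samples. These sizes were chosen so each stage's statistical
claim (exactness, calibration band, rejection rate) is testable with
comfortable margins.

## Known limitations

* The Karlin–Altschul constants are the standard gapped BLOSUM62 values;
  no composition-based adjustment or edge-effect correction is applied,
  so E-values are approximate for very short sequences.
* MCL is dense-matrix; fine for 10³ nodes, not for proteome-scale graphs.
* The 54→33 tissue mapping is a reconstruction and should be reviewed
  before use on real GTEx attribute tables.
* Reproducing published GTEx-scale classifier metrics requires the
  external GTEx v8 download and is out of scope for the test suite; the
  package's claims are about the machinery, validated on ground-truth
  synthetics.
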