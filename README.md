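# ribofam

Vertebrate ribosomal proteins (RPs) are among the most conserved genes in
animals, yet individual RPs range from ~60% to 100% sequence identity
between human and zebrafish, and a handful of paralogs (RPL3L in striated
muscle; RPL10L, RPL39L, RPS4Y2, RPL26L1 in testis) are sharply
tissue-restricted. `ribofam` is an R package, with a set of narrative
analysis scripts, for the two questions this raises:

1. **How do RP sequences group and how conserved is each family?**
   Low-complexity masking → exact all-vs-all Smith–Waterman (BLOSUM62,
   affine gaps 11/1, Karlin–Altschul E < 0.05) → percent-identity network
   (edges at ≥ 50% identity) → from-scratch Markov clustering
   (inflation 1.8, minimum cluster size 3) → per-family conservation
   scored by the best human–zebrafish pair, with a two-sided Wilcoxon
   rank-sum comparison of SSU vs LSU families.
2. **Is tissue-level RP expression conserved across species, or does
   variation come from species?** Min–Max normalisation (per gene or per
   organism) → per-tissue summaries → nested cross-validated multiclass
   tissue classifiers (OVR logistic regression, linear/RBF SVM, random
   forest; 3×90/10 outer splits, 5-fold inner grid search; accuracy,
   macro-F1, multiclass MCC) → cross-species transfer: train on human,
   predict another species' tissues, score the tally of correct
   predictions with the exact one-tailed binomial test
   P(X ≥ k), X ~ Binomial(n, 1/K).

A first-class synthetic-data module generates protein families and
expression matrices with known ground truth (star-phylogeny divergence
with BLOSUM62-propensity substitutions; log-additive expression with
shared tissue effects, species offsets, paralog enrichments and missing
values), so the entire pipeline is testable without downloads. The
intended audience is computational biologists studying gene-family
conservation and cross-species expression, and anyone needing a
self-contained, oracle-tested reference implementation of this analysis
pattern.

## Worked example

```r
library(ribofam)

# --- sequence arm on synthetic families -------------------------------
sim   <- simulate_families(n_families = 3, species = c("Homo", "Mus", "Danio"),
                           divergence = 0.1, n_decoys = 2, seed = 7)
masked <- mask_collection(sim$records)          # CAST-style masking
hits   <- all_vs_all(masked)                    # exact SW, E < 0.05
net    <- build_graph(hits, min_identity = 50, nodes = sim$records$record_id)
fams   <- mcl(net)                              # Markov clustering
fams$n_clusters                                 # 3
length(fams$unassigned)                         # 2  (the decoys)

cons <- conservation_scores(fams, hits,
                            setNames(sim$records$species, sim$records$record_id))
cons[, c("cluster_id", "n_members", "conservation_identity")]
#>   cluster_id n_members conservation_identity
#> 1          1         3                  80.9
#> 2          2         3                  81.5
#> 3          3         3                  80.1

# --- expression arm: does tissue signal transfer across species? ------
expr <- simulate_scenario("tissue_dominant", seed = 7)
tr <- cross_species_transfer(subset_species(expr$m, "Homo"),
                             subset_species(expr$m, "Gallus"),
                             model_spec("linear_svm"), cv_scheme(seed = 7))
sprintf("%d/%d correct, chance %.3f, binomial p = %.3g",
        tr$n_correct, tr$n_test, tr$chance_p0, tr$binomial_p)
#> "12/12 correct, chance 0.333, binomial p = 1.88e-06"
```

The three planted families come back as exactly three clusters with both
random decoys unassigned; within-family identity ~80% reflects the 0.10
per-branch divergence. In the tissue-dominant regime (tissue effects
twice the species offsets) the human-trained classifier predicts every
chicken sample's tissue, and the binomial tail probability says chance
cannot explain it. Rerunning with the `species_dominant` scenario leaves
the same pipeline at chance — the contrast the transfer test is built to
detect.

## Analysis workflow

The `analysis/` scripts run the study end to end on synthetic data,
writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_collection.R` | builds the synthetic RP collection + truth |
| `02_sequence_arm.R` | masking, all-vs-all, MCL, conservation, subunit test |
| `03_expression_overview.R` | scaling, per-tissue summary, t-SNE embedding |
| `04_tissue_classifiers.R` | nested-CV metrics for all four model families |
| `05_cross_species_transfer.R` | transfer tests across simulation regimes |

`run_sequence_arm()` / `run_expression_arm()` orchestrate the same stages
from a single YAML config and write a manifest (parameters, seed, output
checksums) per run.

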