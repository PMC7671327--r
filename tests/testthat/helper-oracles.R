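# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

rf_residues <- function() setdiff(ribofam:::RF_ALPHABET, "X")

random_peptide <- function(n) {
  paste(sample(rf_residues(), n, replace = TRUE), collapse = "")
}

# Independent local-alignment score oracle: Biostrings' own dynamic
# programming implementation (gap of length L costs 11 + L, matching the
# package's BLAST-style convention).
oracle_sw_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = env$BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend, type = "local"))
}

# Minimal hits tibble for graph tests.
make_hits <- function(from, to, identity) {
  n <- length(from)
  tibble::tibble(query_id = from, subject_id = to,
                 raw_score = rep(100, n), bit_score = rep(30, n),
                 e_value = rep(1e-10, n), identity_pct = identity,
                 alignment_length = rep(100L, n),
                 qstart = rep(1L, n), qend = rep(100L, n),
                 sstart = rep(1L, n), send = rep(100L, n))
}

clique_hits <- function(ids, identity = 90) {
  pairs <- t(utils::combn(ids, 2))
  make_hits(pairs[, 1], pairs[, 2], rep(identity, nrow(pairs)))
}

# Run the full sequence pipeline on a simulated collection and return the
# clustering plus truth.
planted_pipeline <- function(seed, n_families = 5, n_decoys = 5,
                             divergence = 0.10, lowcomplex_rate = 0.1) {
  sim <- simulate_families(n_families = n_families, divergence = divergence,
                           n_decoys = n_decoys,
                           lowcomplex_rate = lowcomplex_rate, seed = seed)
  masked <- mask_collection(sim$records)
  hits <- all_vs_all(masked)
  graph <- build_graph(hits, min_identity = 50,
                       nodes = sim$records$record_id)
  list(clustering = mcl(graph), truth = sim$truth, hits = hits)
}

planted_ari <- function(pl) {
  truth <- pl$truth
  assigned <- setNames(rep(0L, nrow(truth)), truth$record_id)
  assigned[pl$clustering$clusters$record_id] <- pl$clustering$clusters$cluster_id
  fam <- !is.na(truth$family_id)
  mclust::adjustedRandIndex(assigned[truth$record_id[fam]],
                            truth$family_id[fam])
}

# One-hot Pearson-correlation oracle for the multiclass MCC (sum of
# per-class covariances, normalised).
oracle_onehot_mcc <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  P <- outer(pred, classes, "==") * 1
  T <- outer(truth, classes, "==") * 1
  num <- sum(vapply(seq_along(classes), function(k) cov(P[, k], T[, k]),
                    numeric(1)))
  den <- sqrt(sum(vapply(seq_along(classes), function(k) cov(P[, k], P[, k]),
                         numeric(1))) *
              sum(vapply(seq_along(classes), function(k) cov(T[, k], T[, k]),
                         numeric(1))))
  if (den == 0) 0 else num / den
}

# Marker-gene "blob" scenario: each tissue over-expresses its own disjoint
# marker set, giving well-separated classes for every model family.
separable_blobs <- function(seed, n_per_tissue = 20, noise_sd = 0.1) {
  tissues <- c("brain", "heart", "kidney")
  markers <- tibble::tibble(gene = sprintf("G%03d", 1:30),
                            tissue = rep(tissues, each = 10), gamma = 5)
  tp <- expression_truth(tissue_sd = 0, species_sd = 0, noise_sd = noise_sd,
                         enrich = markers)
  simulate_expression(n_genes = 30, tissues = tissues, species = "Homo",
                      samples_per_cell = n_per_tissue, params = tp,
                      seed = seed)
}

# Tiny valid collection used across collection_io tests.
tiny_collection <- function() {
  protein_collection(
    gene_symbol = c("RPL1", "RPL1", "RPS2", "RPS2"),
    species = c("Homo", "Homo", "Homo", "Danio"),
    sequence = c(strrep("ACDEFGHIKL", 12), strrep("ACDEFGHIKL", 11),
                 strrep("MNPQRSTVWY", 10), strrep("MNPQRSTVWY", 9)),
    source_accession = c("NP_001", "NP_002", "NP_003", "NP_004"),
    role = c("ref", "iso", "ref", "ref"),
    isoform_index = c(0L, 1L, 0L, 0L))
}
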