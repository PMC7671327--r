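#' Read and validate a pipeline configuration
#'
#' A single YAML file drives both arms; every stated analysis constant
#' (E-value cutoff 0.05, 50% identity threshold, inflation 1.8, minimum
#' cluster size 3, 3x90/10 outer splits, 5 inner folds, binomial
#' threshold 0.1) lives here and is copied verbatim into each run's
#' manifest so no default stays hidden. File paths are checked up front,
#' before any computation.
#'
#' @param path YAML path, or a list with the same structure.
#' @return A validated config list of class `rf_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    seed = 0L,
    output_dir = "results",
    collection = list(fasta = NULL, simulate = NULL),
    expression = list(gct = NULL, crpkm = NULL, simulate_scenario = NULL,
                      tissue_map = NULL,
                      exclude_genes = gender_paralogs(),
                      scaling = "per_gene"),
    scoring = list(gap_open = 11, gap_extend = 1, karlin_lambda = 0.267,
                   karlin_K = 0.041, e_value_cutoff = 0.05),
    masking = list(threshold = 40, gap = 11),
    graph = list(min_identity = 50),
    mcl = list(inflation = 1.8, min_cluster_size = 3, binary_edges = FALSE),
    conservation = list(species_a = "Homo", species_b = "Danio",
                        exclusions = c("RPS27A", "UBA52")),
    cv = list(outer_splits = 3, test_fraction = 0.10, inner_folds = 5),
    models = c("logreg_ovr", "linear_svm", "rbf_svm", "random_forest"),
    transfer = list(p0 = "uniform", alpha = 0.1))
  cfg <- utils::modifyList(defaults, cfg)
  for (p in c(cfg$collection$fasta, cfg$expression$gct, cfg$expression$crpkm,
              cfg$expression$tissue_map)) {
    if (!is.null(p) && !file.exists(p)) stop("configured file missing: ", p)
  }
  if (is.null(cfg$collection$fasta) && is.null(cfg$collection$simulate) &&
      is.null(cfg$expression$gct) && is.null(cfg$expression$crpkm) &&
      is.null(cfg$expression$simulate_scenario))
    stop("config provides no inputs for either arm")
  structure(cfg, class = c("rf_config", "list"))
}

write_manifest <- function(outdir, stage, cfg, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("ribofam")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("class"))],
    output_checksums = as.list(tools::md5sum(unlist(outputs))))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the sequence arm end to end
#'
#' Collection (read or simulated) -> low-complexity masking -> all-vs-all
#' Smith-Waterman -> identity network -> MCL -> conservation scores (and
#' the SSU/LSU comparison when subunits are assignable). Intermediate
#' artifacts are persisted under `cfg$output_dir` together with a manifest
#' recording parameters, seed and output checksums.
#'
#' @param cfg An `rf_config` (or path / list accepted by
#'   [read_pipeline_config()]).
#' @return List: `records`, `summary`, `hits`, `graph`, `clustering`,
#'   `conservation`, `subunit_test` (NULL if not computable), `truth`
#'   (simulation truth or NULL), `manifest` path.
#' @export
run_sequence_arm <- function(cfg) {
  if (!inherits(cfg, "rf_config")) cfg <- read_pipeline_config(cfg)
  outdir <- file.path(cfg$output_dir, "sequence")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(cfg$collection$fasta)) {
    records <- read_collection(cfg$collection$fasta)
  } else if (!is.null(cfg$collection$simulate)) {
    sim_args <- cfg$collection$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- do.call(simulate_families, sim_args)
    records <- sim$records
    truth <- sim$truth
    write_collection(records, file.path(outdir, "collection.fasta"))
    readr::write_tsv(truth, file.path(outdir, "family_truth.tsv"))
  } else stop("sequence arm needs collection$fasta or collection$simulate")
  summ <- summarize_collection(records)
  readr::write_tsv(summ$per_species, file.path(outdir, "collection_summary.tsv"))
  params <- scoring_params(gap_open = cfg$scoring$gap_open,
                           gap_extend = cfg$scoring$gap_extend,
                           karlin_lambda = cfg$scoring$karlin_lambda,
                           karlin_K = cfg$scoring$karlin_K,
                           e_value_cutoff = cfg$scoring$e_value_cutoff)
  masked <- mask_collection(records, threshold = cfg$masking$threshold,
                            gap = cfg$masking$gap)
  hits <- all_vs_all(masked, params)
  write_hits_tsv(hits, file.path(outdir, "hits.tsv"))
  graph <- build_graph(hits, min_identity = cfg$graph$min_identity,
                       nodes = records$record_id)
  clustering <- mcl(graph, mcl_params(
    inflation = cfg$mcl$inflation,
    min_cluster_size = cfg$mcl$min_cluster_size,
    binary_edges = cfg$mcl$binary_edges))
  write_clusters_tsv(clustering, file.path(outdir, "clusters.tsv"))
  species_of <- setNames(records$species, records$record_id)
  gene_of <- setNames(records$gene_symbol, records$record_id)
  conservation <- conservation_scores(clustering, hits, species_of,
                                      species_a = cfg$conservation$species_a,
                                      species_b = cfg$conservation$species_b)
  readr::write_tsv(conservation, file.path(outdir, "conservation.tsv"))
  subunit_test <- NULL
  scored_genes <- gene_of[conservation$pair_a[conservation$scored]]
  if (sum(conservation$scored) >= 4 &&
      !anyNA(default_subunit_map(scored_genes))) {
    subunit_test <- compare_subunit_conservation(
      conservation, gene_of, exclusions = cfg$conservation$exclusions)
    jsonlite::write_json(subunit_test, file.path(outdir, "subunit_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- write_manifest(outdir, "sequence", cfg,
                             list.files(outdir, full.names = TRUE))
  list(records = records, summary = summ, hits = hits, graph = graph,
       clustering = clustering, conservation = conservation,
       subunit_test = subunit_test, truth = truth, manifest = manifest)
}

#' Run the expression arm end to end
#'
#' Expression input (GCT / cRPKM / simulated scenario) -> tissue-category
#' assignment -> gender-paralog exclusion -> Min-Max scaling -> per-tissue
#' summary -> nested-CV classifiers; when the input provides a second
#' species, a cross-species transfer test is run for each non-reference
#' species. Artifacts and a manifest are written under `cfg$output_dir`.
#'
#' @param cfg As in [run_sequence_arm()].
#' @return List: `matrix` (scaled `rf_expr`), `summary`, `cv` (nested-CV
#'   results or NULL), `transfer` (list of `rf_transfer` or NULL),
#'   `truth`, `manifest`.
#' @export
run_expression_arm <- function(cfg) {
  if (!inherits(cfg, "rf_config")) cfg <- read_pipeline_config(cfg)
  outdir <- file.path(cfg$output_dir, "expression")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(cfg$expression$gct)) {
    m <- read_gct(cfg$expression$gct)
  } else if (!is.null(cfg$expression$crpkm)) {
    m <- read_crpkm_tsv(cfg$expression$crpkm)
  } else if (!is.null(cfg$expression$simulate_scenario)) {
    sim <- simulate_scenario(cfg$expression$simulate_scenario, seed = cfg$seed)
    m <- sim$m
    truth <- sim$truth
  } else stop("expression arm needs gct, crpkm or simulate_scenario")
  if (!is.null(cfg$expression$tissue_map))
    m <- assign_tissue_categories(m, cfg$expression$tissue_map)
  if (anyNA(m$sample_meta$tissue_category))
    m$sample_meta$tissue_category <- m$sample_meta$tissue_site
  if (length(cfg$expression$exclude_genes))
    m <- suppressWarnings(
      exclude_gender_paralogs(m, cfg$expression$exclude_genes))
  scaled <- minmax_scale(m, mode = cfg$expression$scaling)
  summ <- tissue_summary(scaled)
  readr::write_tsv(summ, file.path(outdir, "tissue_summary.tsv"))
  scheme <- cv_scheme(outer_splits = cfg$cv$outer_splits,
                      test_fraction = cfg$cv$test_fraction,
                      inner_folds = cfg$cv$inner_folds, seed = cfg$seed)
  specs <- lapply(cfg$models, model_spec, grid = NULL, seed = cfg$seed)
  species <- unique(m$sample_meta$species)
  ref_species <- species[1]
  train_m <- subset_species(m, ref_species)
  cv_res <- NULL
  if (ncol(train_m$values) >= 10) {
    cv_res <- nested_cv(train_m, specs, scheme)
    cv_tab <- dplyr::bind_rows(lapply(cv_res, function(r)
      tibble::tibble(family = r$family, mean_accuracy = r$mean_accuracy,
                     sd_accuracy = r$sd_accuracy,
                     mean_macro_f1 = r$mean_macro_f1,
                     sd_macro_f1 = r$sd_macro_f1,
                     mean_mcc = r$mean_mcc, sd_mcc = r$sd_mcc)))
    readr::write_tsv(cv_tab, file.path(outdir, "cv_metrics.tsv"))
  }
  transfer <- NULL
  others <- setdiff(species, ref_species)
  if (length(others)) {
    transfer <- lapply(others, function(sp)
      cross_species_transfer(train_m, subset_species(m, sp),
                             spec = specs[[1]], scheme = scheme,
                             p0 = cfg$transfer$p0))
    names(transfer) <- others
    tr_tab <- dplyr::bind_rows(lapply(transfer, function(t)
      tibble::tibble(species = t$species, n_test = t$n_test,
                     n_correct = t$n_correct, chance_p0 = t$chance_p0,
                     binomial_p = t$binomial_p)))
    readr::write_tsv(tr_tab, file.path(outdir, "transfer.tsv"))
  }
  manifest <- write_manifest(outdir, "expression", cfg,
                             list.files(outdir, full.names = TRUE))
  list(matrix = scaled, summary = summ, cv = cv_res, transfer = transfer,
       truth = truth, manifest = manifest)
}
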