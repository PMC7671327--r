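# BLOSUM62 background residue frequencies (standard 20-residue set), used
# both for ancestral draws and for substitution propensities.
rf_background_freqs <- function() {
  c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
    E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
    M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
    Y = 0.032, V = 0.073)
}

# Substitution kernel: P(b | a) proportional to p_b * 2^(B62(a,b)/2) for
# b != a — off-diagonal BLOSUM62 exchange propensities, which keeps the
# identity/score relationship realistic for the aligner.
rf_substitution_kernel <- function() {
  bg <- rf_background_freqs()
  res <- names(bg)
  B <- rf_submatrix()[res, res]
  K <- matrix(0, 20, 20, dimnames = list(res, res))
  for (a in res) {
    w <- bg * 2 ^ (B[a, ] / 2)
    w[a] <- 0
    K[a, ] <- w / sum(w)
  }
  K
}

mutate_seq <- function(chars, divergence, kernel, indel_rate = 0.02,
                       min_len = 30L) {
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(colnames(kernel), 1, prob = kernel[a, ]), character(1))
  }
  # rare short indel (deletion), keeping a sane minimum length
  if (runif(1) < indel_rate && length(chars) > min_len + 5L) {
    w <- sample(1:5, 1)
    at <- sample(length(chars) - w, 1)
    chars <- chars[-seq(at, at + w - 1L)]
  }
  chars
}

#' Simulate protein families with known ground truth
#'
#' Generates `n_families` star-phylogeny families: an ancestral sequence
#' per family (length uniform in `len_range`, residues drawn from BLOSUM62
#' background frequencies) diverged independently into each species by
#' i.i.d. substitutions at the per-branch probability `divergence`
#' (replacements follow off-diagonal BLOSUM62 exchange propensities) plus
#' rare short deletions. With probability `paralog_rate` a species also
#' carries a further-diverged duplicated paralog (gene symbol suffixed
#' `L`); with probability `lowcomplex_rate` a homopolymeric run is
#' inserted into a sequence (to exercise the masking stage). Decoys are
#' fresh random sequences carrying no family.
#'
#' @param n_families Number of families.
#' @param species Character vector of species tokens.
#' @param divergence Per-branch substitution probability in [0, 0.9].
#' @param paralog_rate,lowcomplex_rate Per-(family, species) and
#'   per-sequence probabilities.
#' @param n_decoys Number of unrelated random sequences.
#' @param indel_rate Per-branch probability of one short deletion.
#' @param len_range Ancestral length range (default 80-400).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List: `records` (collection tibble), `truth` (tibble:
#'   record_id, family_id — NA for decoys, species, paralog).
#' @export
simulate_families <- function(n_families = 5L, species = c("Homo", "Pan",
                              "Macaca", "Mus", "Gallus", "Danio"),
                              divergence = 0.10, paralog_rate = 0,
                              lowcomplex_rate = 0.1, n_decoys = 5L,
                              indel_rate = 0.02, len_range = c(80L, 400L),
                              seed = 0L) {
  stopifnot(divergence >= 0, divergence <= 0.9, n_families >= 1,
            length(species) >= 1)
  set.seed(seed)
  bg <- rf_background_freqs()
  kernel <- rf_substitution_kernel()
  genes <- character(); specs <- character(); seqs <- character()
  fam <- integer(); para <- logical()
  for (f in seq_len(n_families)) {
    L <- sample(seq(len_range[1], len_range[2]), 1)
    anc <- sample(names(bg), L, replace = TRUE, prob = bg)
    gene <- sprintf("FAM%02d", f)
    for (sp in species) {
      chars <- mutate_seq(anc, divergence, kernel, indel_rate)
      genes <- c(genes, gene); specs <- c(specs, sp)
      seqs <- c(seqs, paste(chars, collapse = ""))
      fam <- c(fam, f); para <- c(para, FALSE)
      if (runif(1) < paralog_rate) {
        pchars <- mutate_seq(mutate_seq(anc, divergence, kernel, indel_rate),
                             divergence, kernel, indel_rate)
        genes <- c(genes, paste0(gene, "L")); specs <- c(specs, sp)
        seqs <- c(seqs, paste(pchars, collapse = ""))
        fam <- c(fam, f); para <- c(para, TRUE)
      }
    }
  }
  if (n_decoys > 0) {
    for (d in seq_len(n_decoys)) {
      L <- sample(seq(len_range[1], len_range[2]), 1)
      genes <- c(genes, sprintf("DECOY%02d", d))
      specs <- c(specs, species[1 + (d - 1) %% length(species)])
      seqs <- c(seqs, paste(sample(names(bg), L, replace = TRUE, prob = bg),
                            collapse = ""))
      fam <- c(fam, NA_integer_); para <- c(para, FALSE)
    }
  }
  # optional low-complexity insertions
  lc <- runif(length(seqs)) < lowcomplex_rate
  for (i in which(lc)) {
    run <- paste(rep(sample(names(bg), 1), sample(20:30, 1)), collapse = "")
    at <- sample(nchar(seqs[i]), 1)
    seqs[i] <- paste0(substr(seqs[i], 1, at), run,
                      substr(seqs[i], at + 1, nchar(seqs[i])))
  }
  records <- protein_collection(gene_symbol = genes, species = specs,
                                sequence = seqs)
  truth <- tibble::tibble(record_id = records$record_id, family_id = fam,
                          species = specs, paralog = para,
                          lowcomplex = lc)
  list(records = records, truth = truth)
}

#' Ground-truth parameters for expression simulation
#'
#' The generative model works on the log scale:
#' `log2(x + 1) = mu_g + alpha_t + beta_s + gamma_gt + eps`,
#' with per-gene baselines `mu_g ~ N(mu_mean, mu_sd^2)`, tissue effects
#' `alpha_t ~ N(0, tissue_sd^2)` shared across species, species offsets
#' `beta_s ~ N(0, species_sd^2)`, optional per-(gene, tissue) paralog
#' enrichments `gamma`, and noise `eps ~ N(0, noise_sd^2)`. Values return
#' to the TPM-like scale as `max(2^y - 1, 0)`; cells go missing at
#' `missing_rate` (cRPKM-style).
#'
#' @param mu_mean,mu_sd Baseline log2 abundance distribution (defaults
#'   6 and 1, a highly expressed gene class).
#' @param tissue_sd,species_sd,noise_sd Effect scales (log2 units).
#' @param missing_rate Per-cell missingness probability.
#' @param enrich Tibble/data.frame with columns `gene`, `tissue`, `gamma`
#'   flagging paralog-style enrichments, or NULL.
#' @param alpha,beta Optional explicit named effect vectors overriding the
#'   random draws.
#' @return A list of class `rf_expr_truth_params`.
#' @export
expression_truth <- function(mu_mean = 6, mu_sd = 1, tissue_sd = 1.0,
                             species_sd = 0.5, noise_sd = 0.25,
                             missing_rate = 0, enrich = NULL,
                             alpha = NULL, beta = NULL) {
  stopifnot(noise_sd >= 0, tissue_sd >= 0, species_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, tissue_sd = tissue_sd,
                 species_sd = species_sd, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 enrich = if (is.null(enrich)) NULL else tibble::as_tibble(enrich),
                 alpha = alpha, beta = beta),
            class = "rf_expr_truth_params")
}

#' Simulate a cross-species expression matrix with known truth
#'
#' @param n_genes Number of genes (ids `G001`, ...; enrichment rows in
#'   `params$enrich` may name any of them).
#' @param tissues,species Character vectors (>= 2 tissues).
#' @param samples_per_cell Samples per (species, tissue) cell: a single
#'   integer or a named-per-species vector.
#' @param params An [expression_truth()] object.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List: `m` (an `rf_expr`, units TPM), `truth` (list with the
#'   realised `mu`, `alpha`, `beta`, `enrich`, `params`).
#' @export
simulate_expression <- function(n_genes = 40L, tissues = c("brain", "heart",
                                "kidney"), species = "Homo",
                                samples_per_cell = 5L,
                                params = expression_truth(), seed = 0L) {
  stopifnot(length(tissues) >= 2L, n_genes >= 1L)
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  mu <- setNames(rnorm(n_genes, params$mu_mean, params$mu_sd), genes)
  alpha <- params$alpha %||%
    setNames(rnorm(length(tissues), 0, params$tissue_sd), tissues)
  beta <- params$beta %||%
    setNames(rnorm(length(species), 0, params$species_sd), species)
  gamma <- matrix(0, n_genes, length(tissues),
                  dimnames = list(genes, tissues))
  if (!is.null(params$enrich) && nrow(params$enrich) > 0) {
    bad <- !(params$enrich$gene %in% genes) | !(params$enrich$tissue %in% tissues)
    if (any(bad)) stop("enrichment rows refer to unknown gene/tissue")
    gamma[cbind(params$enrich$gene, params$enrich$tissue)] <- params$enrich$gamma
  }
  spc <- if (length(samples_per_cell) == 1L && is.null(names(samples_per_cell)))
    setNames(rep(as.integer(samples_per_cell), length(species)), species)
  else samples_per_cell[species]
  cols <- list(); meta <- list()
  for (sp in species) {
    for (tis in tissues) {
      for (r in seq_len(spc[[sp]])) {
        y <- mu + alpha[tis] + beta[sp] + gamma[, tis] +
          rnorm(n_genes, 0, params$noise_sd)
        sid <- if (spc[[sp]] == 1L) paste(sp, tis, sep = ":")
               else paste(sp, tis, r, sep = ":")
        cols[[sid]] <- pmax(2 ^ y - 1, 0)
        meta[[sid]] <- tibble::tibble(sample_id = sid, tissue_site = tis,
                                      tissue_category = tis, species = sp,
                                      donor = as.character(r))
      }
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes
  if (params$missing_rate > 0) {
    mask <- matrix(runif(length(vals)) < params$missing_rate, nrow(vals))
    vals[mask] <- NA_real_
  }
  m <- expression_matrix(vals, dplyr::bind_rows(meta), units = "TPM")
  list(m = m, truth = list(mu = mu, alpha = alpha, beta = beta,
                           gamma = gamma, params = params))
}

#' Subset an expression matrix to one species
#'
#' @param m An `rf_expr`.
#' @param species Species token(s) to keep.
#' @return The subset `rf_expr`.
#' @export
subset_species <- function(m, species) {
  keep <- m$sample_meta$species %in% species
  if (!any(keep)) stop("no samples for species ",
                       paste(species, collapse = ", "))
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  out$sample_meta <- m$sample_meta[keep, ]
  out
}

#' Named simulation scenarios
#'
#' Three parameter regimes shipped as YAML under
#' `inst/extdata/scenarios/`: `tissue_dominant` (tissue effects twice the
#' species offsets — the regime in which cross-species transfer should
#' succeed), `species_dominant` (no tissue signal, strong species
#' offsets — transfer should be at chance) and `null` (no tissue or
#' species signal — classifier calibration).
#'
#' @param name Scenario name or a YAML path of the same shape.
#' @return List of arguments for [simulate_expression()].
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name
          else system.file("extdata", "scenarios", paste0(name, ".yaml"),
                           package = "ribofam")
  if (!nzchar(path) || !file.exists(path)) stop("unknown scenario: ", name)
  cfg <- yaml::read_yaml(path)
  list(n_genes = cfg$n_genes, tissues = cfg$tissues, species = cfg$species,
       samples_per_cell = unlist(cfg$samples_per_cell),
       params = expression_truth(tissue_sd = cfg$tissue_sd,
                                 species_sd = cfg$species_sd,
                                 noise_sd = cfg$noise_sd,
                                 missing_rate = cfg$missing_rate %||% 0))
}

#' Simulate a shipped scenario
#'
#' @param name Scenario name (see [load_scenario()]).
#' @param seed Integer seed.
#' @return As [simulate_expression()].
#' @export
simulate_scenario <- function(name, seed = 0L) {
  args <- load_scenario(name)
  simulate_expression(n_genes = args$n_genes, tissues = args$tissues,
                      species = args$species,
                      samples_per_cell = args$samples_per_cell,
                      params = args$params, seed = seed)
}
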