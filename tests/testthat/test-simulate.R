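test_that("zero divergence yields identical family members", {
  sim <- simulate_families(n_families = 2, species = c("Homo", "Mus", "Danio"),
                           divergence = 0, indel_rate = 0,
                           lowcomplex_rate = 0, n_decoys = 0, seed = 1)
  for (f in 1:2) {
    seqs <- sim$records$sequence[sim$truth$family_id == f]
    expect_equal(length(unique(seqs)), 1L)
  }
  hits <- all_vs_all(setNames(sim$records$sequence, sim$records$record_id))
  expect_true(all(hits$identity_pct == 100))
})

test_that("fixed seeds give bit-identical synthetic data", {
  s1 <- simulate_families(seed = 42)
  s2 <- simulate_families(seed = 42)
  expect_identical(s1, s2)
  e1 <- simulate_expression(seed = 42)
  e2 <- simulate_expression(seed = 42)
  expect_identical(e1, e2)
})

test_that("branch divergence ~12.5% lands near 75% pairwise identity", {
  # two branches at p = 0.125 each: expected pairwise identity about
  # (1-p)^2 plus a small coincidental-match term -> ~75-78%
  ids <- c()
  for (seed in 1:10) {
    sim <- simulate_families(n_families = 2, species = c("Homo", "Danio"),
                             divergence = 0.125, indel_rate = 0,
                             lowcomplex_rate = 0, n_decoys = 0, seed = seed)
    for (f in 1:2) {
      pair <- sim$records$sequence[sim$truth$family_id == f]
      a <- strsplit(pair[1], "")[[1]]
      b <- strsplit(pair[2], "")[[1]]
      ids <- c(ids, 100 * mean(a == b))  # direct identity oracle
    }
  }
  expect_gt(mean(ids), 70)
  expect_lt(mean(ids), 80)
})

test_that("decoys stay unconnected at the 50% identity threshold", {
  connected <- 0L
  for (seed in 1:10) {
    pl <- planted_pipeline(seed, n_families = 2, n_decoys = 3,
                           lowcomplex_rate = 0)
    decoys <- pl$truth$record_id[is.na(pl$truth$family_id)]
    strong <- pl$hits[pl$hits$identity_pct >= 50, ]
    if (any(decoys %in% c(strong$query_id, strong$subject_id)))
      connected <- connected + 1L
  }
  expect_lte(connected, 1L)  # >= 95% of seeds clean, allow one
})

test_that("paralogs and low-complexity runs appear at the requested rates", {
  sim <- simulate_families(n_families = 10, species = c("Homo", "Mus"),
                           paralog_rate = 1, lowcomplex_rate = 1,
                           n_decoys = 0, seed = 11)
  expect_equal(sum(sim$truth$paralog), 20L)  # one per family x species
  expect_true(all(grepl("L$", sim$records$gene_symbol[sim$truth$paralog])))
  masked <- mask_collection(sim$records)
  expect_gt(mean(masked$masked_fraction > 0), 0.9)
})

test_that("degenerate expression parameters give constant genes scaling to 0", {
  tp <- expression_truth(tissue_sd = 0, species_sd = 0, noise_sd = 0)
  sim <- simulate_expression(n_genes = 5, tissues = c("a", "b"),
                             samples_per_cell = 3, params = tp, seed = 12)
  expect_true(all(apply(sim$m$values, 1, function(r) length(unique(r))) == 1))
  s <- minmax_scale(sim$m, "per_gene")
  expect_true(all(s$values == 0))
})

test_that("planted testis enrichment shows up after scaling in every seed", {
  tissues <- c("brain", "heart", "testis")
  enrich <- tibble::tibble(gene = "G001", tissue = "testis", gamma = 5)
  for (seed in 1:20) {
    sim <- simulate_expression(n_genes = 10, tissues = tissues,
                               samples_per_cell = 4,
                               params = expression_truth(enrich = enrich),
                               seed = seed)
    s <- minmax_scale(sim$m, "per_gene")
    testis <- s$sample_meta$tissue_category == "testis"
    gap <- mean(s$values["G001", testis]) - mean(s$values["G001", !testis])
    expect_gt(gap, 0.5)
  }
})

test_that("generated values are non-negative and missingness is calibrated", {
  tp <- expression_truth(missing_rate = 0.2)
  sim <- simulate_expression(n_genes = 30, tissues = c("a", "b", "c"),
                             samples_per_cell = 10, params = tp, seed = 13)
  v <- sim$m$values
  expect_true(all(v[!is.na(v)] >= 0))
  n <- length(v)
  expected <- 0.2 * n
  sd2 <- 2 * sqrt(n * 0.2 * 0.8)
  expect_true(abs(sum(is.na(v)) - expected) <= sd2)
})

test_that("regression on the design recovers planted effects within 3 SE", {
  sim <- simulate_expression(n_genes = 20, tissues = c("a", "b", "c"),
                             species = c("Homo", "Gallus"),
                             samples_per_cell = 6, seed = 14)
  y <- as.vector(log2(sim$m$values + 1))
  meta <- sim$m$sample_meta
  df <- data.frame(
    y = y,
    gene = factor(rep(rownames(sim$m$values), times = ncol(sim$m$values))),
    tissue = factor(rep(meta$tissue_category, each = nrow(sim$m$values))),
    species = factor(rep(meta$species, each = nrow(sim$m$values))))
  fit <- lm(y ~ gene + tissue + species, data = df)
  co <- summary(fit)$coefficients
  alpha <- sim$truth$alpha
  for (t in c("b", "c")) {
    est <- co[paste0("tissue", t), ]
    expect_lt(abs(est["Estimate"] - (alpha[t] - alpha["a"])),
              3 * est["Std. Error"] + 1e-6)
  }
  beta <- sim$truth$beta
  est <- co["speciesHomo", ]
  expect_lt(abs(est["Estimate"] - (beta["Homo"] - beta["Gallus"])),
            3 * est["Std. Error"] + 1e-6)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_families(divergence = 0.95))
  expect_error(expression_truth(noise_sd = -1))
  expect_error(simulate_expression(n_genes = 5, tissues = "only-one"),
               "tissues")
  expect_error(simulate_expression(
    n_genes = 5, tissues = c("a", "b"),
    params = expression_truth(enrich = tibble::tibble(
      gene = "nope", tissue = "a", gamma = 1))), "unknown")
})

test_that("scenario files load and drive the generator", {
  for (nm in c("tissue_dominant", "species_dominant", "null")) {
    args <- load_scenario(nm)
    expect_true(length(args$tissues) >= 2)
    sim <- simulate_scenario(nm, seed = 1)
    expect_s3_class(sim$m, "rf_expr")
  }
  expect_error(load_scenario("no-such-scenario"), "unknown")
})
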