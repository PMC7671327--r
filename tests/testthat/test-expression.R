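tiny_expr <- function(vals = NULL, species = NULL) {
  if (is.null(vals)) {
    vals <- matrix(c(0, 5, 10, 7, 7, 7), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  }
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    tissue_site = rep_len(c("brain", "heart", "kidney"), ncol(vals)),
    species = species %||% rep("Homo", ncol(vals)))
  expression_matrix(vals, meta)
}

test_that("GCT round trip preserves values and dimensions", {
  sim <- simulate_expression(n_genes = 5, tissues = c("brain", "heart"),
                             samples_per_cell = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(sim$m, path)
  back <- read_gct(path)
  expect_equal(back$values, sim$m$values, tolerance = 1e-12)
  expect_equal(colnames(back$values), sim$m$sample_meta$sample_id)
})

test_that("malformed GCT inputs fail with informative errors", {
  p1 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("not-gct", "2\t2"), p1)
  expect_error(read_gct(p1), "#1.2")
  p2 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "oops\t2",
               "Name\tDescription\ts1\ts2", "g1\tg1\t1\t2", "g2\tg2\t3\t4"), p2)
  expect_error(read_gct(p2), "line 2")
  p3 <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t2",
               "Name\tDescription\ts1\ts2", "g1\tg1\t1\t2", "g2\tg2\t3\t4"), p3)
  expect_error(read_gct(p3), "mismatch")
})

test_that("cRPKM tables carry the missing-value mask through a round trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tHomo:brain\tHomo:heart\tDanio:brain",
               "g1\t1.5\tNA\t2.0",
               "g2\t0\t3.25\t"), p)
  m <- read_crpkm_tsv(p)
  expect_equal(m$units, "cRPKM")
  expect_true(is.na(m$values["g1", "Homo:heart"]))
  expect_true(is.na(m$values["g2", "Danio:brain"]))
  expect_equal(m$sample_meta$species, c("Homo", "Homo", "Danio"))
  expect_equal(m$sample_meta$tissue_site, c("brain", "heart", "brain"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_crpkm_tsv(m, p2)
  back <- read_crpkm_tsv(p2)
  expect_equal(back$values, m$values)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tHomo:brain", "g1\t-2"), p3)
  expect_error(read_crpkm_tsv(p3), "negative")
})

test_that("Min-Max scaling maps rows to [0,1], constants to 0, idempotently", {
  m <- tiny_expr()
  s <- minmax_scale(m, "per_gene")
  expect_equal(unname(s$values["g1", ]), c(0, 0.5, 1))
  expect_equal(unname(s$values["g2", ]), c(0, 0, 0))
  expect_equal(minmax_scale(s, "per_gene")$values, s$values)  # idempotent
  # order preserved within each gene
  expect_equal(order(s$values["g1", ]), order(m$values["g1", ]))
})

test_that("per-organism scaling spans [0,1] independently per species", {
  vals <- matrix(c(100, 200, 1, 2,
                   150, 250, 1.5, 2.5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("h1", "h2", "d1", "d2")))
  m <- tiny_expr(vals, species = c("Homo", "Homo", "Danio", "Danio"))
  s <- minmax_scale(m, "per_organism")
  for (sp in c("Homo", "Danio")) {
    block <- s$values[, m$sample_meta$species == sp]
    expect_equal(min(block), 0)
    expect_equal(max(block), 1)
    # direct recomputation oracle
    raw <- vals[, m$sample_meta$species == sp]
    expect_equal(block, (raw - min(raw)) / (max(raw) - min(raw)))
  }
})

test_that("missing cells are excluded from scaling and stay missing", {
  vals <- matrix(c(0, NA, 10), nrow = 1,
                 dimnames = list("g1", c("s1", "s2", "s3")))
  s <- minmax_scale(tiny_expr(vals), "per_gene")
  expect_true(is.na(s$values[1, 2]))
  expect_equal(unname(s$values[1, c(1, 3)]), c(0, 1))
})

test_that("tissue categories come from the mapping, erroring on gaps", {
  m <- tiny_expr()
  ident <- setNames(unique(m$sample_meta$tissue_site),
                    unique(m$sample_meta$tissue_site))
  m2 <- assign_tissue_categories(m, ident)
  expect_equal(m2$sample_meta$tissue_category, m2$sample_meta$tissue_site)
  expect_error(assign_tissue_categories(m, ident[-1]), "unmapped")
})

test_that("the shipped GTEx map keeps cerebellum apart from other brain sites", {
  map <- gtex_tissue_map()
  expect_length(map, 54L)
  expect_equal(length(unique(map)), 33L)
  expect_equal(unname(map["Brain - Cerebellum"]), "cerebellum")
  expect_equal(unname(map["Brain - Cortex"]), "brain")
  expect_false(map["Brain - Cerebellum"] == map["Brain - Cortex"])
  expect_equal(unname(map["Cells - EBV-transformed lymphocytes"]),
               "lymphocytes")
})

test_that("gender-paralog exclusion drops exactly the listed genes", {
  genes <- c(sprintf("RP%02d", 1:83), gender_paralogs())
  vals <- matrix(runif(89 * 4), nrow = 89,
                 dimnames = list(genes, paste0("s", 1:4)))
  m <- tiny_expr(vals)
  m2 <- exclude_gender_paralogs(m)
  expect_equal(nrow(m2$values), 83L)
  expect_false(any(gender_paralogs() %in% rownames(m2$values)))
  expect_equal(exclude_gender_paralogs(m, character())$values, m$values)
  expect_warning(m3 <- exclude_gender_paralogs(m2), "ignored")
  expect_equal(nrow(m3$values), 83L)  # idempotent
})

test_that("tissue summaries are permutation-invariant and mass-consistent", {
  set.seed(401)
  sim <- simulate_expression(n_genes = 10, tissues = c("ovary", "liver",
                             "heart"), samples_per_cell = 4,
                             params = expression_truth(
                               tissue_sd = 0, species_sd = 0, noise_sd = 0.2,
                               alpha = c(ovary = 2, liver = -2, heart = 0)),
                             seed = 2)
  s <- minmax_scale(sim$m, "per_gene")
  summ <- tissue_summary(s)
  expect_equal(summ$tissue_category[1], "ovary")   # planted high
  expect_equal(summ$tissue_category[nrow(summ)], "liver")  # planted low
  # mean of means weighted by cell count equals the global mean
  ncells <- summ$n_samples * nrow(s$values)
  expect_equal(sum(summ$mean * ncells) / sum(ncells), mean(s$values))
  # permuting samples changes nothing
  perm <- sample(ncol(s$values))
  s2 <- s
  s2$values <- s$values[, perm]
  s2$sample_meta <- s$sample_meta[perm, ]
  expect_equal(tissue_summary(s2), summ)
})

test_that("a uniform category summarises to its value", {
  vals <- matrix(0.5, nrow = 2, ncol = 3,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  m <- tiny_expr(vals)
  m$sample_meta$tissue_category <- "brain"
  summ <- tissue_summary(m)
  expect_equal(summ$mean, 0.5)
  expect_equal(summ$n_samples, 3L)
})

test_that("t-SNE embedding is deterministic and separates planted blobs", {
  sim <- separable_blobs(seed = 3, n_per_tissue = 12)
  s <- minmax_scale(sim$m, "per_gene")
  emb1 <- embed_tsne(s, perplexity = 5, max_iter = 400, seed = 0)
  emb2 <- embed_tsne(s, perplexity = 5, max_iter = 400, seed = 0)
  expect_identical(emb1, emb2)
  skip_if_not_installed("cluster")
  d <- dist(as.matrix(emb1[, c("dim1", "dim2")]))
  sil <- cluster::silhouette(as.integer(factor(emb1$tissue_category)), d)
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("duplicate samples embed near-identically", {
  sim <- separable_blobs(seed = 4, n_per_tissue = 30)
  s <- minmax_scale(sim$m, "per_gene")
  v <- s$values
  v[, 2] <- v[, 1]  # exact duplicate
  s$values <- v
  emb <- embed_tsne(s, perplexity = 25, max_iter = 600, seed = 0)
  xy <- as.matrix(emb[, c("dim1", "dim2")])
  dup_dist <- sqrt(sum((xy[1, ] - xy[2, ])^2))
  diam <- max(dist(xy))
  expect_lt(dup_dist, 0.01 * diam)
})

test_that("t-SNE refuses too-small sample counts for the perplexity", {
  sim <- simulate_expression(n_genes = 5, tissues = c("a", "b"),
                             samples_per_cell = 2, seed = 5)
  expect_error(embed_tsne(minmax_scale(sim$m, "per_gene"), perplexity = 30),
               "perplexity")
})
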