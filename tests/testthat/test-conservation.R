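make_clustering <- function(members) {
  clusters <- dplyr::bind_rows(lapply(seq_along(members), function(i)
    tibble::tibble(cluster_id = i, record_id = members[[i]])))
  structure(list(clusters = clusters, unassigned = character(),
                 n_clusters = length(members), converged = TRUE,
                 iterations = 1L), class = "rf_clustering")
}

test_that("conservation takes the maximum cross-species identity per cluster", {
  res <- make_clustering(list(c("g1_Homo_ref_0", "g1_Danio_ref_0",
                                "g1_Mus_ref_0")))
  species_of <- c(g1_Homo_ref_0 = "Homo", g1_Danio_ref_0 = "Danio",
                  g1_Mus_ref_0 = "Mus")
  hits <- make_hits(c("g1_Homo_ref_0", "g1_Danio_ref_0", "g1_Homo_ref_0"),
                    c("g1_Danio_ref_0", "g1_Homo_ref_0", "g1_Mus_ref_0"),
                    c(75, 82, 95))
  sc <- conservation_scores(res, hits, species_of)
  expect_true(sc$scored)
  expect_equal(sc$conservation_identity, 82)
  expect_equal(sc$pair_a, "g1_Homo_ref_0")
  expect_equal(sc$pair_b, "g1_Danio_ref_0")
})

test_that("clusters lacking a reference species are flagged unscored", {
  res <- make_clustering(list(c("g1_Homo_ref_0", "g1_Mus_ref_0")))
  species_of <- c(g1_Homo_ref_0 = "Homo", g1_Mus_ref_0 = "Mus")
  hits <- make_hits("g1_Homo_ref_0", "g1_Mus_ref_0", 90)
  sc <- conservation_scores(res, hits, species_of)
  expect_false(sc$scored)
  expect_true(is.na(sc$conservation_identity))
})

test_that("conservation is invariant to adding within-species hits", {
  res <- make_clustering(list(c("a_Homo", "b_Homo", "c_Danio")))
  species_of <- c(a_Homo = "Homo", b_Homo = "Homo", c_Danio = "Danio")
  base <- make_hits("a_Homo", "c_Danio", 77)
  extra <- dplyr::bind_rows(base, make_hits("a_Homo", "b_Homo", 99))
  s1 <- conservation_scores(res, base, species_of)
  s2 <- conservation_scores(res, extra, species_of)
  expect_equal(s2$conservation_identity, s1$conservation_identity)
})

test_that("conservation score equals brute-force max over synthetic clusters", {
  set.seed(301)
  for (rep in 1:5) {
    ids_a <- paste0("h", 1:3)
    ids_b <- paste0("z", 1:3)
    species_of <- c(setNames(rep("Homo", 3), ids_a),
                    setNames(rep("Danio", 3), ids_b))
    pairs <- expand.grid(q = ids_a, s = ids_b, stringsAsFactors = FALSE)
    idn <- runif(nrow(pairs), 50, 100)
    hits <- make_hits(pairs$q, pairs$s, idn)
    res <- make_clustering(list(c(ids_a, ids_b)))
    sc <- conservation_scores(res, hits, species_of)
    expect_equal(sc$conservation_identity, max(idn))
  }
})

test_that("subunit comparison reproduces the exact rank-sum p-value", {
  sc <- tibble::tibble(
    cluster_id = 1:6, n_members = 3L,
    conservation_identity = c(1, 2, 3, 4, 5, 6),
    pair_a = c("RPS1_h", "RPS2_h", "RPS3_h", "RPL1_h", "RPL2_h", "RPL3_h"),
    pair_b = c("RPS1_z", "RPS2_z", "RPS3_z", "RPL1_z", "RPL2_z", "RPL3_z"),
    scored = TRUE)
  gene_of <- setNames(sub("_.$", "", c(sc$pair_a, sc$pair_b)),
                      c(sc$pair_a, sc$pair_b))
  out <- compare_subunit_conservation(sc, gene_of)
  expect_true(out$exact)
  expect_equal(out$p_value, 0.1)   # exact enumeration of C(6,3) assignments
  expect_equal(out$n_ssu, 3L)
  expect_equal(out$median_diff, 2 - 5)
})

test_that("identical groups give p = 1 and empty groups error", {
  sc <- tibble::tibble(
    cluster_id = 1:4, n_members = 3L,
    conservation_identity = c(80, 90, 80, 90),
    pair_a = c("RPS1_h", "RPS2_h", "RPL1_h", "RPL2_h"),
    pair_b = c("RPS1_z", "RPS2_z", "RPL1_z", "RPL2_z"),
    scored = TRUE)
  gene_of <- setNames(sub("_.$", "", c(sc$pair_a, sc$pair_b)),
                      c(sc$pair_a, sc$pair_b))
  out <- compare_subunit_conservation(sc, gene_of)
  expect_equal(out$p_value, 1.0)
  ssu_only <- sc[1:2, ]
  expect_error(compare_subunit_conservation(ssu_only, gene_of), "empty")
})

test_that("excluded genes drop their clusters from the comparison", {
  sc <- tibble::tibble(
    cluster_id = 1:5, n_members = 3L,
    conservation_identity = c(70, 71, 72, 73, 10),
    pair_a = c("RPS1_h", "RPS2_h", "RPL1_h", "RPL2_h", "RPS27A_h"),
    pair_b = c("RPS1_z", "RPS2_z", "RPL1_z", "RPL2_z", "RPS27A_z"),
    scored = TRUE)
  gene_of <- setNames(sub("_.$", "", c(sc$pair_a, sc$pair_b)),
                      c(sc$pair_a, sc$pair_b))
  out <- compare_subunit_conservation(sc, gene_of,
                                      exclusions = c("RPS27A", "UBA52"))
  expect_equal(out$n_ssu + out$n_lsu, 4L)
})

test_that("a planted +4 shift is detected reliably at realistic group sizes", {
  set.seed(303)
  ssu_genes <- sprintf("RPS%d", 1:33)
  lsu_genes <- sprintf("RPL%d", 1:47)
  genes <- c(ssu_genes, lsu_genes)
  pair_a <- paste0(genes, "_h"); pair_b <- paste0(genes, "_z")
  gene_of <- setNames(c(genes, genes), c(pair_a, pair_b))
  detected <- 0L
  for (rep in 1:200) {
    sc <- tibble::tibble(
      cluster_id = seq_along(genes), n_members = 3L,
      conservation_identity = c(rnorm(33, 90, 5), rnorm(47, 86, 5)),
      pair_a = pair_a, pair_b = pair_b, scored = TRUE)
    out <- compare_subunit_conservation(sc, gene_of)
    if (out$p_value < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 0.9 * 200)
})

test_that("subunits derive from RP nomenclature with known special cases", {
  expect_equal(default_subunit_map(c("RPS6", "RPSA", "FAU", "RPL3", "RPLP0",
                                     "UBA52", "ACTB")),
               c("SSU", "SSU", "SSU", "LSU", "LSU", "LSU", NA))
})
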