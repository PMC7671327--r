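#' Within-cluster sequence conservation between two reference species
#'
#' For every cluster, selects the pair of members from `species_a` and
#' `species_b` (by default human and zebrafish, the most distant pair in
#' the vertebrate set) with the highest alignment identity and uses that
#' identity as the cluster's conservation score. Clusters lacking members
#' from either species get no score and are flagged.
#'
#' @param result An `rf_clustering` from [mcl()].
#' @param hits A hits tibble covering cross-species pairs.
#' @param species_of Named character vector mapping record_id to species
#'   (e.g. built from a collection tibble).
#' @param species_a,species_b Species tokens to compare (defaults "Homo",
#'   "Danio").
#' @return A tibble: `cluster_id`, `n_members`, `conservation_identity`
#'   (NA when unscorable), `pair_a`, `pair_b`, `scored`.
#' @export
conservation_scores <- function(result, hits, species_of,
                                species_a = "Homo", species_b = "Danio") {
  memb <- result$clusters
  sp_q <- species_of[hits$query_id]
  sp_s <- species_of[hits$subject_id]
  cross <- (sp_q == species_a & sp_s == species_b) |
           (sp_q == species_b & sp_s == species_a)
  ch <- hits[which(cross), ]
  cl_ids <- sort(unique(memb$cluster_id))
  rows <- lapply(cl_ids, function(cid) {
    ids <- memb$record_id[memb$cluster_id == cid]
    has_a <- any(species_of[ids] == species_a)
    has_b <- any(species_of[ids] == species_b)
    sub <- ch[ch$query_id %in% ids & ch$subject_id %in% ids, ]
    if (!has_a || !has_b || nrow(sub) == 0L) {
      return(tibble::tibble(cluster_id = cid, n_members = length(ids),
                            conservation_identity = NA_real_,
                            pair_a = NA_character_, pair_b = NA_character_,
                            scored = FALSE))
    }
    best <- sub[which.max(sub$identity_pct), ]
    a_first <- species_of[best$query_id] == species_a
    tibble::tibble(cluster_id = cid, n_members = length(ids),
                   conservation_identity = best$identity_pct,
                   pair_a = if (a_first) best$query_id else best$subject_id,
                   pair_b = if (a_first) best$subject_id else best$query_id,
                   scored = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Default ribosomal-subunit assignment from gene symbols
#'
#' RP nomenclature encodes the subunit in the symbol: `RPS*`, `RPSA` and
#' `FAU` (eS30 precursor) are small-subunit (SSU) proteins; `RPL*`,
#' `RPLP*` and `UBA52` (eL40 precursor) are large-subunit (LSU). Symbols
#' that match neither pattern return NA and must be supplied explicitly.
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector `"SSU"`/`"LSU"`/NA.
#' @export
default_subunit_map <- function(genes) {
  out <- rep(NA_character_, length(genes))
  out[grepl("^RPS", genes) | genes %in% c("FAU", "RPSA")] <- "SSU"
  out[grepl("^RPL", genes) | genes %in% c("UBA52")] <- "LSU"
  out
}

#' Compare conservation between ribosomal subunits
#'
#' Splits scored clusters into SSU and LSU groups (clusters listing any
#' gene in `exclusions` — e.g. the mixed RPS27A/UBA52 fusion-precursor
#' cluster — are dropped) and tests for a location shift with a two-sided
#' Wilcoxon rank-sum test: exact when both groups have at most 25
#' observations and the data are untied, normal approximation with tie
#' correction otherwise. Both median and mean differences are reported
#' because either could be quoted as the "shift".
#'
#' @param scores Conservation tibble from [conservation_scores()].
#' @param subunit_of Named character vector gene -> "SSU"/"LSU", or NULL to
#'   use [default_subunit_map()] on the gene parsed from `pair_a`.
#' @param gene_of Named character vector record_id -> gene symbol.
#' @param exclusions Character vector of gene symbols whose clusters are
#'   excluded.
#' @return A list: `statistic`, `p_value`, `n_ssu`, `n_lsu`,
#'   `median_ssu`, `median_lsu`, `median_diff`, `mean_ssu`, `mean_lsu`,
#'   `mean_diff`, `exact`.
#' @export
compare_subunit_conservation <- function(scores, gene_of, subunit_of = NULL,
                                         exclusions = character()) {
  sc <- scores[scores$scored, ]
  if (nrow(sc) == 0L) stop("no scored clusters")
  genes <- gene_of[sc$pair_a]
  if (length(exclusions)) {
    drop <- genes %in% exclusions | gene_of[sc$pair_b] %in% exclusions
    sc <- sc[!drop, ]
    genes <- genes[!drop]
  }
  su <- if (is.null(subunit_of)) default_subunit_map(genes) else subunit_of[genes]
  if (anyNA(su))
    stop("unlabelled subunit for gene(s): ",
         paste(unique(genes[is.na(su)]), collapse = ", "))
  x <- sc$conservation_identity[su == "SSU"]
  y <- sc$conservation_identity[su == "LSU"]
  if (length(x) == 0L || length(y) == 0L)
    stop("one subunit group is empty (SSU n=", length(x),
         ", LSU n=", length(y), ")")
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  wt <- wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = !exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_ssu = length(x), n_lsu = length(y),
       median_ssu = median(x), median_lsu = median(y),
       median_diff = median(x) - median(y),
       mean_ssu = mean(x), mean_lsu = mean(y),
       mean_diff = mean(x) - mean(y), exact = exact)
}
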