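#' Build a percent-identity similarity graph from alignment hits
#'
#' Keeps an undirected edge for every hit at or above the identity
#' threshold (default 50%, chosen to avoid spurious links between
#' non-ortholog RPs); edge weight is the identity percentage. Every id seen
#' in the hit list (and any extra ids supplied) is retained as a node, so
#' sequences whose hits all fall below threshold appear as degree-0 nodes.
#'
#' @param hits A hits tibble ([all_vs_all()] output, already E-filtered).
#' @param min_identity Identity threshold in percent (default 50).
#' @param nodes Optional character vector of node ids to include even if
#'   absent from `hits`.
#' @return A list of class `rf_graph` with `nodes` (character) and `edges`
#'   (tibble: from, to, weight; symmetric-unique, no self-loops).
#' @export
build_graph <- function(hits, min_identity = 50, nodes = NULL) {
  ids <- union(unique(c(hits$query_id, hits$subject_id)), nodes %||% character())
  keep <- hits$identity_pct >= min_identity & hits$query_id != hits$subject_id
  e <- hits[keep, c("query_id", "subject_id", "identity_pct")]
  names(e) <- c("from", "to", "weight")
  # canonical order + dedup keeping the max weight
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  if (nrow(e) > 0) {
    e <- e |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop")
  }
  structure(list(nodes = sort(ids), edges = e), class = "rf_graph")
}

#' Markov clustering parameters
#'
#' @param inflation Entrywise-power inflation (> 1; default 1.8, the
#'   granularity used throughout this analysis).
#' @param min_cluster_size Clusters smaller than this dissolve into the
#'   unassigned set (default 3).
#' @param self_loop One of `"max"` (self-loop weight = node's maximum
#'   incident edge weight, Biolayout-style, scale-free against identity
#'   weights) or a positive number used for all nodes.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iterations,convergence_tol Iteration controls.
#' @param binary_edges If TRUE, edge weights are replaced by 1 before
#'   clustering (exposed because upstream tooling is ambiguous about
#'   weighted vs binary input).
#' @return A list of class `rf_mcl_params`.
#' @export
mcl_params <- function(inflation = 1.8, min_cluster_size = 3L,
                       self_loop = "max", prune_threshold = 1e-5,
                       max_iterations = 200L, convergence_tol = 1e-6,
                       binary_edges = FALSE) {
  stopifnot(inflation > 1, min_cluster_size >= 1)
  structure(list(inflation = inflation,
                 min_cluster_size = as.integer(min_cluster_size),
                 self_loop = self_loop, prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 binary_edges = isTRUE(binary_edges)),
            class = "rf_mcl_params")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' From-scratch implementation of the standard MCL process: self-loops are
#' added (weight = the node's maximum incident weight, or 1 for isolated
#' nodes), columns are normalised to a stochastic matrix, then expansion
#' (matrix squaring) alternates with inflation (entrywise power followed by
#' column renormalisation) and pruning of small entries until the matrix
#' changes by less than `convergence_tol` or `max_iterations` is reached
#' (the latter emits a warning and interprets the current matrix).
#'
#' Clusters are read off attractor rows: attractors are nodes with positive
#' return probability; attractor systems (mutually attracting groups) are
#' merged, and each cluster is an attractor system plus the nodes it
#' attracts. A node attracted by several systems joins the largest cluster
#' (ties: lowest cluster id). Clusters below `min_cluster_size` dissolve
#' into the unassigned set.
#'
#' @param graph An `rf_graph` from [build_graph()].
#' @param params An [mcl_params()] object.
#' @return A list of class `rf_clustering`: `clusters` (tibble cluster_id,
#'   record_id), `unassigned` (character), `n_clusters`, `converged`,
#'   `iterations`.
#' @export
mcl <- function(graph, params = mcl_params()) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L)
    return(structure(list(clusters = tibble::tibble(cluster_id = integer(),
                                                    record_id = character()),
                          unassigned = character(), n_clusters = 0L,
                          converged = TRUE, iterations = 0L),
                     class = "rf_clustering"))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges) > 0) {
    w <- if (params$binary_edges) rep(1, nrow(graph$edges)) else graph$edges$weight
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  loop <- if (identical(params$self_loop, "max")) {
    mx <- apply(A, 1, max)
    ifelse(mx > 0, mx, 1)
  } else rep(as.numeric(params$self_loop), n)
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    M2 <- M %*% M                       # expansion
    M2 <- M2 ^ params$inflation         # inflation
    M2[M2 < params$prune_threshold] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; interpreting current matrix", call. = FALSE)
  interpret_mcl(M, nodes, params, converged, it)
}

interpret_mcl <- function(M, nodes, params, converged = TRUE, it = NA_integer_) {
  eps <- params$prune_threshold
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0L) attractors <- seq_along(nodes)  # degenerate
  # attractor systems: union attractors that attract one another
  sys_id <- seq_along(attractors)
  for (ai in seq_along(attractors)) {
    for (bi in seq_along(attractors)) {
      a <- attractors[ai]; b <- attractors[bi]
      if (ai < bi && (M[a, b] > eps || M[b, a] > eps)) {
        old <- sys_id[bi]; sys_id[sys_id == old] <- sys_id[ai]
      }
    }
  }
  systems <- split(attractors, sys_id)
  # raw clusters: system members + all nodes they attract
  raw <- lapply(systems, function(sys) {
    member <- unique(c(sys, which(colSums(M[sys, , drop = FALSE]) > eps)))
    sort(member)
  })
  # order clusters deterministically: by size desc, then first node id
  ord <- order(-vapply(raw, length, integer(1)),
               vapply(raw, function(m) nodes[m[1]], character(1)))
  raw <- raw[ord]
  # resolve overlaps: largest cluster wins (ties: lowest cluster_id = first)
  assigned <- rep(NA_integer_, length(nodes))
  for (ci in seq_along(raw)) {
    take <- raw[[ci]][is.na(assigned[raw[[ci]]])]
    assigned[take] <- ci
  }
  # dissolve small clusters
  tab <- table(assigned)
  small <- as.integer(names(tab)[tab < params$min_cluster_size])
  assigned[assigned %in% small] <- NA_integer_
  keep <- sort(unique(assigned[!is.na(assigned)]))
  remap <- match(assigned, keep)
  clusters <- tibble::tibble(cluster_id = remap[!is.na(remap)],
                             record_id = nodes[!is.na(remap)]) |>
    dplyr::arrange(.data$cluster_id, .data$record_id)
  structure(list(clusters = clusters,
                 unassigned = sort(nodes[is.na(remap)]),
                 n_clusters = length(keep),
                 converged = converged, iterations = it),
            class = "rf_clustering")
}

#' Write clusters as two-column TSV
#'
#' Unassigned nodes are emitted with the sentinel cluster id 0.
#'
#' @param result An `rf_clustering`.
#' @param path Output TSV path.
#' @export
write_clusters_tsv <- function(result, path) {
  out <- dplyr::bind_rows(
    result$clusters,
    tibble::tibble(cluster_id = 0L, record_id = result$unassigned))
  readr::write_tsv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
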