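#' Construct an expression matrix container
#'
#' Genes are rows, samples columns; missing cells are NA. Sample metadata
#' carries the collection site, the (optional) tissue category, the
#' species and the (optional) donor.
#'
#' @param values Numeric matrix (genes x samples) with rownames and
#'   colnames; non-missing entries must be finite and >= 0.
#' @param sample_meta Tibble with columns `sample_id`, `tissue_site`,
#'   `species` and optionally `tissue_category`, `donor`; rows must match
#'   `colnames(values)`.
#' @param units `"TPM"` or `"cRPKM"` (recorded, not converted).
#' @param scaled NULL, `"per_gene"` or `"per_organism"`.
#' @return A list of class `rf_expr`.
#' @export
expression_matrix <- function(values, sample_meta, units = "TPM",
                              scaled = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  v <- values[!is.na(values)]
  if (any(!is.finite(v)) || any(v < 0))
    stop("expression values must be finite and non-negative")
  sample_meta <- tibble::as_tibble(sample_meta)
  if (!all(c("sample_id", "tissue_site", "species") %in% names(sample_meta)))
    stop("sample_meta needs sample_id, tissue_site, species")
  if (!identical(sample_meta$sample_id, colnames(values)))
    stop("sample_meta rows must match matrix columns (same order)")
  if (!"tissue_category" %in% names(sample_meta))
    sample_meta$tissue_category <- NA_character_
  if (!"donor" %in% names(sample_meta)) sample_meta$donor <- NA_character_
  structure(list(values = values, sample_meta = sample_meta,
                 units = units, scaled = scaled),
            class = "rf_expr")
}

#' @method print rf_expr
#' @export
print.rf_expr <- function(x, ...) {
  cat("<rf_expr> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$units, "]",
      if (!is.null(x$scaled)) paste0(", scaled ", x$scaled) else "",
      "; missing ", sum(is.na(x$values)), " cells\n", sep = "")
  invisible(x)
}

#' Read a GCT (v1.2/1.3) expression file
#'
#' GCT is the GTEx distribution format: a `#1.2` (or `#1.3`) version line,
#' a dimension line `n_genes<TAB>n_samples`, then a header row
#' `Name<TAB>Description<TAB><sample ids...>` and one row per gene.
#'
#' @param path GCT file path.
#' @param sample_meta Optional sample-attribute tibble (joined on
#'   `sample_id`); when absent, sites default to the sample id and species
#'   to `"Homo"`.
#' @param units Recorded unit label.
#' @return An `rf_expr`.
#' @export
read_gct <- function(path, sample_meta = NULL, units = "TPM") {
  lines <- readr::read_lines(path, n_max = 2)
  if (length(lines) < 2 || !grepl("^#1\\.[23]", lines[1]))
    stop("not a GCT file (missing #1.2/#1.3 version line): ", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2]))
    stop("malformed GCT dimension line (line 2): '", lines[2], "'")
  body <- readr::read_tsv(path, skip = 2, show_col_types = FALSE,
                          progress = FALSE)
  if (!all(c("Name", "Description") %in% names(body)[1:2]))
    stop("GCT header must start with Name and Description columns")
  vals <- as.matrix(body[, -(1:2)])
  rownames(vals) <- body$Name
  if (nrow(vals) != dims[1] || ncol(vals) != dims[2])
    stop("GCT dimension mismatch: declared ", dims[1], "x", dims[2],
         ", found ", nrow(vals), "x", ncol(vals))
  meta <- tibble::tibble(sample_id = colnames(vals))
  if (!is.null(sample_meta)) {
    meta <- dplyr::left_join(meta, tibble::as_tibble(sample_meta),
                             by = "sample_id")
  }
  if (!"tissue_site" %in% names(meta)) meta$tissue_site <- meta$sample_id
  if (!"species" %in% names(meta)) meta$species <- "Homo"
  expression_matrix(vals, meta, units = units)
}

#' Write an `rf_expr` as GCT v1.2
#'
#' @param m An `rf_expr`.
#' @param path Output path.
#' @export
write_gct <- function(m, path) {
  writeLines(c("#1.2", paste(nrow(m$values), ncol(m$values), sep = "\t")),
             path)
  body <- tibble::tibble(Name = rownames(m$values),
                         Description = rownames(m$values))
  body <- dplyr::bind_cols(body, tibble::as_tibble(m$values))
  readr::write_tsv(body, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a cRPKM table (genes x species-tissue columns)
#'
#' Column names encode species and tissue as `<Species>:<Tissue>`
#' (separator configurable). NA tokens become missing cells; negative
#' values are rejected.
#'
#' @param path TSV path; first column holds gene ids.
#' @param na_tokens Strings treated as missing (default `"NA"`, `"NaN"`,
#'   empty).
#' @param sep Species/tissue separator in column names (default `":"`).
#' @return An `rf_expr` with units `"cRPKM"`.
#' @export
read_crpkm_tsv <- function(path, na_tokens = c("NA", "NaN", ""), sep = ":") {
  x <- readr::read_tsv(path, na = na_tokens, show_col_types = FALSE,
                       progress = FALSE)
  genes <- as.character(x[[1]])
  vals <- as.matrix(x[, -1])
  rownames(vals) <- genes
  if (any(vals[!is.na(vals)] < 0)) stop("negative expression value in ", path)
  parts <- strsplit(colnames(vals), sep, fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) != 2L))
    stop("column names must be <Species>", sep, "<Tissue>")
  meta <- tibble::tibble(
    sample_id = colnames(vals),
    tissue_site = vapply(parts, `[`, character(1), 2),
    species = vapply(parts, `[`, character(1), 1))
  meta$tissue_category <- meta$tissue_site
  expression_matrix(vals, meta, units = "cRPKM")
}

#' Write an `rf_expr` as a cRPKM-style TSV
#'
#' @param m An `rf_expr` whose sample ids follow `<Species>:<Tissue>`.
#' @param path Output path.
#' @export
write_crpkm_tsv <- function(m, path) {
  body <- tibble::tibble(gene = rownames(m$values))
  body <- dplyr::bind_cols(body, tibble::as_tibble(m$values))
  readr::write_tsv(body, path, na = "NA")
  invisible(path)
}

#' Min-Max scaling of expression values
#'
#' Rescales non-missing values linearly to [0, 1] either per gene (each
#' gene row independently: `(x - min)/(max - min)`) or per organism (one
#' mapping per species computed over all of that species' cells).
#' Constant units map to all-0 (they carry no signal but keep the matrix
#' dense for classifiers). Missing cells are excluded from min/max and
#' stay missing. The operation is idempotent.
#'
#' @param m An `rf_expr`.
#' @param mode `"per_gene"` or `"per_organism"`.
#' @return The scaled `rf_expr` (with `scaled` set).
#' @export
minmax_scale <- function(m, mode = c("per_gene", "per_organism")) {
  mode <- match.arg(mode)
  v <- m$values
  if (mode == "per_gene") {
    for (g in seq_len(nrow(v))) v[g, ] <- minmax_vec(v[g, ])
  } else {
    for (sp in unique(m$sample_meta$species)) {
      cols <- which(m$sample_meta$species == sp)
      block <- v[, cols, drop = FALSE]
      rng <- range(block, na.rm = TRUE)
      v[, cols] <- if (rng[1] == rng[2]) 0 * block
                   else (block - rng[1]) / (rng[2] - rng[1])
    }
  }
  out <- m
  out$values <- v
  out$scaled <- mode
  out
}

minmax_vec <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  rng <- range(x[ok])
  if (rng[1] == rng[2]) { x[ok] <- 0; return(x) }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Assign samples to tissue categories
#'
#' Maps each sample's collection site to a coarser tissue category (e.g.
#' the GTEx 54-site to 33-category grouping shipped in
#' `inst/extdata/gtex_tissue_map.yaml`, which keeps cerebellum separate
#' from other brain sites and cell lines as their own categories).
#'
#' @param m An `rf_expr`.
#' @param mapping Named character vector or list site -> category, or a
#'   path to a YAML file of the same shape.
#' @return The `rf_expr` with `tissue_category` filled.
#' @export
assign_tissue_categories <- function(m, mapping) {
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
    mapping <- yaml::read_yaml(mapping)
  mapping <- unlist(mapping)
  sites <- m$sample_meta$tissue_site
  missing_sites <- setdiff(unique(sites), names(mapping))
  if (length(missing_sites))
    stop("unmapped tissue site(s): ", paste(missing_sites, collapse = "; "))
  out <- m
  out$sample_meta$tissue_category <- unname(mapping[sites])
  out
}

#' Shipped GTEx site-to-category mapping
#'
#' @return Named character vector (54 sites -> 33 categories).
#' @export
gtex_tissue_map <- function() {
  unlist(yaml::read_yaml(system.file("extdata", "gtex_tissue_map.yaml",
                                     package = "ribofam")))
}

#' Gender-associated RP paralogs excluded from classification
#' @export
gender_paralogs <- function() {
  c("RPL10L", "RPS4X", "RPS4Y1", "RPS4Y2", "RPL39L", "RPL26L1")
}

#' Drop gender-associated paralog genes
#'
#' Removes the listed genes (by default the six sex-associated RP
#' paralogs, taking a GTEx-shaped matrix from 89 to 83 RPs). Absent genes
#' are ignored with a warning; the operation is idempotent.
#'
#' @param m An `rf_expr`.
#' @param genes Gene symbols to drop.
#' @return The reduced `rf_expr`.
#' @export
exclude_gender_paralogs <- function(m, genes = gender_paralogs()) {
  if (length(genes) == 0L) return(m)
  absent <- setdiff(genes, rownames(m$values))
  if (length(absent))
    warning("gene(s) not in matrix, ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- !(rownames(m$values) %in% genes)
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Per-category expression summary
#'
#' One row per tissue category with the arithmetic mean of all (scaled)
#' values, quartiles and sample count, ranked by decreasing mean — the
#' numbers behind a per-tissue global-RP-expression bar/box plot.
#'
#' @param m A scaled, categorised `rf_expr`.
#' @return Tibble: `tissue_category`, `n_samples`, `mean`, `q25`,
#'   `median`, `q75`, `rank`.
#' @export
tissue_summary <- function(m) {
  if (anyNA(m$sample_meta$tissue_category))
    stop("assign tissue categories first")
  cats <- split(seq_len(ncol(m$values)), m$sample_meta$tissue_category)
  rows <- lapply(names(cats), function(cat) {
    v <- as.vector(m$values[, cats[[cat]], drop = FALSE])
    v <- v[!is.na(v)]
    tibble::tibble(tissue_category = cat, n_samples = length(cats[[cat]]),
                   mean = mean(v), q25 = quantile(v, 0.25, names = FALSE),
                   median = median(v), q75 = quantile(v, 0.75, names = FALSE))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean))
  out$rank <- seq_len(nrow(out))
  out
}

#' t-SNE embedding of samples (plumbing)
#'
#' Embeds samples (columns) by their scaled expression profiles with
#' Rtsne. The seed is set immediately before the call so a fixed seed
#' reproduces the embedding exactly.
#'
#' @param m A scaled `rf_expr` without missing values.
#' @param dims 2 or 3.
#' @param perplexity t-SNE perplexity (default 30; requires
#'   `n_samples - 1 >= 3 * perplexity`).
#' @param max_iter Iterations (default 1000).
#' @param seed RNG seed (default 0).
#' @return Tibble: `sample_id`, `tissue_category`, `dim1`, `dim2`
#'   (, `dim3`).
#' @export
embed_tsne <- function(m, dims = 2, perplexity = 30, max_iter = 1000,
                       seed = 0) {
  x <- t(m$values)
  if (anyNA(x)) stop("t-SNE requires a complete matrix")
  if (nrow(x) - 1 < 3 * perplexity)
    stop("too few samples (", nrow(x), ") for perplexity ", perplexity,
         "; need n_samples - 1 >= 3 * perplexity")
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = dims, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = FALSE)
  out <- tibble::as_tibble(fit$Y, .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(
    sample_id = m$sample_meta$sample_id,
    tissue_category = m$sample_meta$tissue_category), out)
}
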