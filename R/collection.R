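#' Header dialect for curated RP collections
#'
#' The curated collection encodes each entry's metadata in its FASTA header as
#' `<Gene>_<Species>_<role>_<n>`, e.g. `RPL39L_Macaca_ref_0`. The gene symbol
#' may itself contain the separator-free punctuation used by RP nomenclature
#' (`RPS28-like`, `RPL40-precursor`); parsing therefore splits from the right:
#' the last token is the isoform index, the one before it the role, the one
#' before that the species, and everything remaining is the gene symbol.
#'
#' @param sep Single-character field separator (default `"_"`).
#' @param ref_token,iso_token Tokens marking reference and isoform records.
#' @return A list of class `rf_header_dialect`.
#' @export
header_dialect <- function(sep = "_", ref_token = "ref", iso_token = "iso") {
  stopifnot(nchar(sep) == 1L, ref_token != iso_token)
  structure(list(sep = sep, ref_token = ref_token, iso_token = iso_token),
            class = "rf_header_dialect")
}

# 20 standard residues + X (mask/ambiguity)
RF_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Build a protein record collection
#'
#' A collection is a tibble with one row per sequence and the columns
#' `record_id`, `gene_symbol`, `species`, `source_accession`, `role`
#' (`"ref"` or `"iso"`), `isoform_index`, `translated` (TRUE for entries
#' rescued from six-frame translated DNA) and `sequence`. Sequences are
#' upper-cased and non-standard residues (B, Z, J, U, O, `*`) are normalised
#' to `X` with a warning, since all downstream scoring is defined on the
#' 20-residue + X alphabet.
#'
#' @param gene_symbol,species,sequence Character vectors (recycled to equal
#'   length).
#' @param source_accession Optional accession strings ("" if unknown).
#' @param role `"ref"`/`"iso"`; if `NA`, call [mark_reference_isoforms()].
#' @param isoform_index Non-negative integer index within (gene, species).
#' @param translated Logical flag for translated-DNA origin.
#' @param dialect A [header_dialect()] used to build `record_id`s.
#' @return A validated collection tibble.
#' @export
protein_collection <- function(gene_symbol, species, sequence,
                               source_accession = "", role = "ref",
                               isoform_index = 0L, translated = FALSE,
                               dialect = header_dialect()) {
  rec <- tibble::tibble(
    gene_symbol = as.character(gene_symbol),
    species = as.character(species),
    source_accession = as.character(source_accession),
    role = as.character(role),
    isoform_index = as.integer(isoform_index),
    translated = as.logical(translated),
    sequence = normalize_residues(as.character(sequence))
  )
  rec$record_id <- make_record_id(rec, dialect)
  validate_collection(rec[, c("record_id", "gene_symbol", "species",
                              "source_accession", "role", "isoform_index",
                              "translated", "sequence")])
}

make_record_id <- function(records, dialect = header_dialect()) {
  paste(records$gene_symbol, records$species, records$role,
        records$isoform_index, sep = dialect$sep)
}

normalize_residues <- function(seqs) {
  seqs <- toupper(seqs)
  bad <- grepl("[BZJUO*]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-standard residues ",
            "(B/Z/J/U/O/*); normalised to X", call. = FALSE)
    seqs <- gsub("[BZJUO*]", "X", seqs)
  }
  seqs
}

#' Validate a collection
#'
#' Checks the structural invariants of a curated collection: non-empty
#' sequences over the 20+X alphabet, unique record ids, exactly one `ref`
#' record per (gene, species) group, and reference length at least the
#' length of every isoform in its group.
#'
#' @param records A collection tibble.
#' @return The records, invisibly valid (errors otherwise).
#' @export
validate_collection <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (any(!nzchar(records$sequence)))
    stop("empty sequence in record(s): ",
         paste(records$record_id[!nzchar(records$sequence)], collapse = ", "))
  ok <- grepl(paste0("^[", paste(RF_ALPHABET, collapse = ""), "]+$"),
              records$sequence)
  if (any(!ok))
    stop("invalid residues in record(s): ",
         paste(records$record_id[!ok], collapse = ", "))
  if (anyDuplicated(records$record_id))
    stop("duplicate record_id(s): ",
         paste(unique(records$record_id[duplicated(records$record_id)]),
               collapse = ", "))
  if (any(!records$role %in% c("ref", "iso")))
    stop("role must be 'ref' or 'iso'")
  grp <- split(seq_len(nrow(records)),
               paste(records$gene_symbol, records$species, sep = "\r"))
  for (idx in grp) {
    nref <- sum(records$role[idx] == "ref")
    if (nref != 1L)
      stop("group (", records$gene_symbol[idx[1]], ", ",
           records$species[idx[1]], ") has ", nref,
           " 'ref' records; expected exactly 1")
    reflen <- nchar(records$sequence[idx][records$role[idx] == "ref"])
    if (any(nchar(records$sequence[idx]) > reflen))
      stop("group (", records$gene_symbol[idx[1]], ", ",
           records$species[idx[1]], ") has an isoform longer than its ref")
  }
  records
}

#' Read a curated collection from multi-FASTA
#'
#' Parses a protein multi-FASTA whose headers follow the collection's
#' encoding (see [header_dialect()]). Unparseable headers are reported
#' together with their entry numbers.
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param dialect A [header_dialect()].
#' @return A collection tibble (zero rows for an empty file).
#' @export
read_collection <- function(fasta_path, dialect = header_dialect()) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) == 0L) {
    return(protein_collection(character(), character(), character()))
  }
  headers <- sub("\\s.*$", "", names(aa))  # id = first whitespace-free token
  parts <- strsplit(headers, dialect$sep, fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 4L, logical(1))
  roles <- vapply(parts, function(p) if (length(p) >= 2) p[length(p) - 1L] else "",
                  character(1))
  idx_tok <- vapply(parts, function(p) p[length(p)], character(1))
  bad <- bad | !(roles %in% c(dialect$ref_token, dialect$iso_token)) |
    !grepl("^[0-9]+$", idx_tok)
  if (any(bad))
    stop("unparseable FASTA header(s) at entry ",
         paste(which(bad), collapse = ", "), ": ",
         paste(utils::head(headers[bad], 5), collapse = "; "))
  gene <- vapply(parts, function(p)
    paste(p[seq_len(length(p) - 3L)], collapse = dialect$sep), character(1))
  species <- vapply(parts, function(p) p[length(p) - 2L], character(1))
  desc <- sub("^\\S+\\s*", "", names(aa))  # optional "accession=... translated"
  acc <- ifelse(grepl("accession=\\S+", desc),
                sub(".*accession=(\\S+).*", "\\1", desc), "")
  rec <- protein_collection(
    gene_symbol = gene, species = species,
    sequence = as.character(aa),
    source_accession = acc,
    role = ifelse(roles == dialect$ref_token, "ref", "iso"),
    isoform_index = as.integer(idx_tok),
    translated = grepl("\\btranslated\\b", desc),
    dialect = dialect
  )
  if (any(!nzchar(as.character(aa))))
    stop("empty sequence for entry ",
         paste(which(!nzchar(as.character(aa))), collapse = ", "))
  rec
}

#' Write a collection to multi-FASTA
#'
#' Emits standard FASTA with 60-column wrapping and headers in the
#' collection encoding; accession and translated-origin flags are carried in
#' the description so that read/write round-trips losslessly.
#'
#' @param records A valid collection tibble.
#' @param fasta_path Output path.
#' @param dialect A [header_dialect()].
#' @return `fasta_path`, invisibly.
#' @export
write_collection <- function(records, fasta_path, dialect = header_dialect()) {
  validate_collection(records)
  ids <- make_record_id(records, dialect)
  if (anyDuplicated(ids))
    stop("record_id collision: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  desc <- ifelse(nzchar(records$source_accession),
                 paste0(" accession=", records$source_accession), "")
  desc <- paste0(desc, ifelse(records$translated, " translated", ""))
  aa <- Biostrings::AAStringSet(setNames(records$sequence,
                                         paste0(ids, desc)))
  Biostrings::writeXStringSet(aa, fasta_path, width = 60L)
  invisible(fasta_path)
}

#' Assign reference/isoform roles by sequence length
#'
#' Within each (gene, species) group the longest sequence becomes the
#' reference (`ref`, index 0) and the remaining sequences become isoforms
#' (`iso`) numbered 1..k in decreasing length. Ties are broken by
#' lexicographically smaller source accession, then by input order, so the
#' result is invariant to record shuffling when accessions are distinct.
#' The operation is idempotent.
#'
#' @param records A collection tibble (roles may be arbitrary).
#' @param dialect A [header_dialect()] used to rebuild record ids.
#' @return The collection with roles, indices and record ids reassigned.
#' @export
mark_reference_isoforms <- function(records, dialect = header_dialect()) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$gene_symbol, records$species, sep = "\r")
  out <- records
  for (idx in split(seq_len(nrow(records)), key)) {
    o <- idx[order(-nchar(records$sequence[idx]),
                   records$source_accession[idx],
                   seq_along(idx))]
    out$role[o[1]] <- "ref"
    out$isoform_index[o[1]] <- 0L
    if (length(o) > 1L) {
      out$role[o[-1]] <- "iso"
      out$isoform_index[o[-1]] <- seq_len(length(o) - 1L)
    }
  }
  out$record_id <- make_record_id(out, dialect)
  validate_collection(out)
}

#' Summarise a collection (per-species gene and sequence counts)
#'
#' Reproduces the collection-overview numbers: per species, the number of
#' distinct RP genes identified and the total number of protein sequences
#' (isoforms included), plus per-(gene, species) isoform counts and
#' translated-origin flags.
#'
#' @param records A collection tibble.
#' @return A list with `per_species` (tibble: species, n_genes,
#'   n_sequences), `per_gene_species` (tibble: gene_symbol, species,
#'   n_isoforms, translated), `n_records`, `n_genes`.
#' @export
summarize_collection <- function(records) {
  if (nrow(records) == 0L) {
    return(list(
      per_species = tibble::tibble(species = character(), n_genes = integer(),
                                   n_sequences = integer()),
      per_gene_species = tibble::tibble(gene_symbol = character(),
                                        species = character(),
                                        n_isoforms = integer(),
                                        translated = logical()),
      n_records = 0L, n_genes = 0L))
  }
  per_species <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_symbol),
                     n_sequences = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$species)
  per_gene_species <- records |>
    dplyr::group_by(.data$gene_symbol, .data$species) |>
    dplyr::summarise(n_isoforms = dplyr::n(),
                     translated = any(.data$translated), .groups = "drop")
  list(per_species = per_species,
       per_gene_species = per_gene_species,
       n_records = nrow(records),
       n_genes = dplyr::n_distinct(records$gene_symbol))
}
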