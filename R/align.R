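#' Exact local alignment of two protein sequences
#'
#' Full Smith-Waterman with affine gaps (Gotoh), no heuristic seeding: at
#' collection scale correctness is preferred over BLAST-style speed.
#' Identity is computed over aligned columns; an `X` (masked or ambiguous)
#' never counts as a match even against another `X`. Significance follows
#' Karlin-Altschul statistics with a pairwise search space m*n (query
#' length times subject length): bit score `(lambda*S - ln K) / ln 2` and
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param a,b Residue strings (non-empty, 20+X alphabet).
#' @param params A [scoring_params()] object.
#' @param query_id,subject_id Optional ids carried into the result.
#' @return A one-row tibble: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `e_value`, `identity_pct`, `alignment_length`,
#'   `qstart`, `qend`, `sstart`, `send`.
#' @export
local_align <- function(a, b, params = scoring_params(),
                        query_id = "query", subject_id = "subject") {
  stopifnot(nzchar(a), nzchar(b))
  res <- sw_align_cpp(encode_seq(a), encode_seq(b), params$matrix,
                      params$gap_open, params$gap_extend, rf_x_code())
  hit_row(query_id, subject_id, res, nchar(a), nchar(b), params)
}

hit_row <- function(qid, sid, res, m, n, params) {
  s <- res$score
  m <- unname(m); n <- unname(n)
  tibble::tibble(
    query_id = qid, subject_id = sid,
    raw_score = s,
    bit_score = (params$karlin_lambda * s - log(params$karlin_K)) / log(2),
    e_value = params$karlin_K * m * n * exp(-params$karlin_lambda * s),
    identity_pct = if (res$align_length > 0)
      100 * res$n_identical / res$align_length else 0,
    alignment_length = res$align_length,
    qstart = res$qstart, qend = res$qend,
    sstart = res$sstart, send = res$send)
}

#' All-vs-all significant local alignments
#'
#' Aligns every unordered pair of (typically masked) sequences and keeps
#' hits with `e_value < params$e_value_cutoff`. Self-hits are excluded and
#' each unordered pair appears once (local alignment is symmetric, so the
#' collapsed hit carries the pair's maximal identity by construction).
#'
#' Significance here follows the database convention BLAST uses for a
#' search against a collection: the E-value search space is the query
#' length times the total residue count of the whole collection, so the
#' 0.05 cutoff budgets about one chance hit per twenty *searches*, not per
#' pair. (Single-pair [local_align()] keeps the pairwise m*n convention.)
#'
#' @param seqs Named character vector of sequences, or a masked-collection
#'   tibble from [mask_collection()] (the `masked` column is used).
#' @param params A [scoring_params()].
#' @param progress Unused hook for callers that want to report progress.
#' @return A hits tibble as in [local_align()], one row per significant
#'   pair.
#' @export
all_vs_all <- function(seqs, params = scoring_params(), progress = NULL) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$masked, seqs$record_id)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  enc <- lapply(seqs, encode_seq)
  lens <- nchar(seqs)
  db_len <- sum(lens)
  out <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      res <- sw_align_cpp(enc[[i]], enc[[j]], params$matrix,
                          params$gap_open, params$gap_extend, rf_x_code())
      ev <- params$karlin_K * lens[i] * db_len *
        exp(-params$karlin_lambda * res$score)
      if (ev < params$e_value_cutoff) {
        k <- k + 1L
        out[[k]] <- hit_row(names(seqs)[i], names(seqs)[j], res,
                            lens[i], db_len, params)
      }
    }
  }
  if (k == 0L) return(empty_hits())
  dplyr::bind_rows(out[seq_len(k)])
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 raw_score = numeric(), bit_score = numeric(),
                 e_value = numeric(), identity_pct = numeric(),
                 alignment_length = integer(), qstart = integer(),
                 qend = integer(), sstart = integer(), send = integer())
}

#' Six-frame translated rescue search
#'
#' Translates a DNA sequence in all six reading frames (standard genetic
#' code; ambiguous codons containing N translate to X; stop codons split
#' the translation into segments) and locally aligns a protein query
#' against every segment, reporting hits under the E-value cutoff together
#' with their frame and 1-based DNA coordinates on the forward strand.
#' As in [all_vs_all()], the E-value search space is the query length
#' times the total translated length over all six frames (the TBLASTN
#' database convention), so the cutoff controls chance hits per search
#' rather than per segment.
#'
#' @param protein_query Residue string.
#' @param dna DNA string over A/C/G/T/N.
#' @param params A [scoring_params()].
#' @param min_segment Minimum translated segment length to consider.
#' @return A hits tibble with extra columns `frame` (+1..+3, -1..-3),
#'   `dna_start`, `dna_end`. Empty if `nchar(dna) < 3`.
#' @export
six_frame_search <- function(protein_query, dna, params = scoring_params(),
                             min_segment = 5L) {
  stopifnot(nzchar(protein_query))
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) stop("DNA must be over A/C/G/T/N")
  if (nchar(dna) < 3L) {
    out <- empty_hits()
    out$frame <- integer(); out$dna_start <- integer(); out$dna_end <- integer()
    return(out)
  }
  L <- nchar(dna)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  # first pass: collect all translated segments so the search space is known
  segments <- list()
  for (fr in 1:3) {
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) fwd else rev
      if (length(s) - fr + 1L < 3L) next
      sub <- Biostrings::subseq(s, start = fr)
      sub <- Biostrings::subseq(sub, start = 1L,
                                width = 3L * (length(sub) %/% 3L))
      if (length(sub) < 3L) next
      pep <- suppressWarnings(as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "solve")))
      pep <- chartr("*", "$", gsub("[BZJUO]", "X", pep))
      segs <- strsplit(pep, "$", fixed = TRUE)[[1]]
      offset <- 0L
      for (seg in segs) {
        if (nchar(seg) >= min_segment)
          segments[[length(segments) + 1L]] <-
            list(seg = seg, frame = strand * fr, fr = fr, offset = offset)
        offset <- offset + nchar(seg) + 1L  # +1 for the stop codon
      }
    }
  }
  db_len <- sum(vapply(segments, function(x) nchar(x$seg), integer(1)))
  qenc <- encode_seq(protein_query)
  m <- nchar(protein_query)
  rows <- list()
  for (sg in segments) {
    res <- sw_align_cpp(qenc, encode_seq(sg$seg), params$matrix,
                        params$gap_open, params$gap_extend, rf_x_code())
    hit <- hit_row("query", "segment", res, m, db_len, params)
    if (hit$e_value < params$e_value_cutoff && hit$alignment_length > 0) {
      # aa positions (within segment) -> nt positions on this strand
      aa0 <- sg$offset + hit$sstart - 1L
      nt_start <- sg$fr + 3L * aa0
      nt_end <- sg$fr + 3L * (sg$offset + hit$send) - 1L
      if (sg$frame < 0L) {  # map back to forward-strand coordinates
        tmp <- L - nt_end + 1L
        nt_end <- L - nt_start + 1L
        nt_start <- tmp
      }
      hit$frame <- sg$frame
      hit$dna_start <- nt_start
      hit$dna_end <- nt_end
      rows[[length(rows) + 1L]] <- hit
    }
  }
  if (length(rows) == 0L) {
    out <- empty_hits()
    out$frame <- integer(); out$dna_start <- integer(); out$dna_end <- integer()
    return(out)
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$e_value)
}

#' Read/write hits as BLAST outfmt-6 style TSV
#'
#' Columns: qseqid, sseqid, pident, length, evalue, bitscore, qstart, qend,
#' sstart, send, score.
#'
#' @param hits A hits tibble.
#' @param path TSV path.
#' @return `path` / a hits tibble.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$identity_pct, length = hits$alignment_length,
    evalue = hits$e_value, bitscore = hits$bit_score,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send, score = hits$raw_score)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    query_id = as.character(x$qseqid), subject_id = as.character(x$sseqid),
    raw_score = x$score, bit_score = x$bitscore, e_value = x$evalue,
    identity_pct = x$pident, alignment_length = as.integer(x$length),
    qstart = as.integer(x$qstart), qend = as.integer(x$qend),
    sstart = as.integer(x$sstart), send = as.integer(x$send))
}
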