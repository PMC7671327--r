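#' Mask compositionally biased (low-complexity) segments
#'
#' Detects low-complexity regions the way CAST-style maskers do: the
#' sequence is locally aligned against an unbounded homopolymer of each of
#' the 20 residue types under BLOSUM62 with a linear gap penalty. Because
#' every mismatch scores better than a deletion at the default gap cost, the
#' optimal local segment is the maximum-sum subarray of the per-position
#' scores against that residue (found with Kadane's algorithm). While any
#' homopolymer score exceeds `threshold`, the occurrences of the offending
#' residue inside its optimal segment are replaced by `X` and the search
#' repeats; residue types are processed in order of decreasing score, ties
#' broken alphabetically, so the result is deterministic.
#'
#' @param seq A residue string over the 20+X alphabet.
#' @param threshold Score threshold above which a segment is masked
#'   (default 40, the conventional CAST cutoff).
#' @param gap Linear gap penalty used in the homopolymer alignment
#'   (default 11).
#' @return A list of class `rf_masked` with `original`, `masked` and
#'   `masked_fraction` (share of positions turned to X).
#' @export
mask_low_complexity <- function(seq, threshold = 40, gap = 11) {
  if (!nzchar(seq)) stop("cannot mask an empty sequence")
  submat <- rf_submatrix()
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (any(!chars %in% RF_ALPHABET))
    stop("sequence contains residues outside the 20+X alphabet")
  residues <- sort(setdiff(RF_ALPHABET, "X"))
  work <- chars
  repeat {
    best <- best_homopolymer_segment(work, residues, submat, gap)
    if (best$score <= threshold) break
    sel <- seq(best$start, best$end)
    hit <- work[sel] == best$residue
    if (!any(hit)) break  # biased segment carries none of the scored residue
    work[sel][hit] <- "X"
  }
  n_x <- sum(work == "X") - sum(chars == "X")
  structure(list(original = paste(chars, collapse = ""),
                 masked = paste(work, collapse = ""),
                 masked_fraction = n_x / length(chars)),
            class = "rf_masked")
}

# Best local homopolymer alignment over all residue types.
# Deterministic preference: highest score, then alphabetical residue.
best_homopolymer_segment <- function(chars, residues, submat, gap) {
  best <- list(score = -Inf, residue = NA_character_, start = 0L, end = 0L)
  for (r in residues) {
    v <- pmax(submat[chars, r], -gap)
    seg <- max_subarray(v)
    if (seg$sum > best$score) best <- list(score = seg$sum, residue = r,
                                           start = seg$start, end = seg$end)
  }
  best
}

# Kadane's maximum-sum subarray with leftmost-longest deterministic ties.
max_subarray <- function(v) {
  best_sum <- -Inf; best_start <- 1L; best_end <- 1L
  cur <- 0; cur_start <- 1L
  for (i in seq_along(v)) {
    if (cur <= 0) { cur <- v[i]; cur_start <- i } else cur <- cur + v[i]
    if (cur > best_sum) { best_sum <- cur; best_start <- cur_start; best_end <- i }
  }
  list(sum = best_sum, start = best_start, end = best_end)
}

#' Mask every sequence in a collection
#'
#' @param records A collection tibble.
#' @param threshold,gap Passed to [mask_low_complexity()].
#' @return A tibble with `record_id`, `original`, `masked`,
#'   `masked_fraction`.
#' @export
mask_collection <- function(records, threshold = 40, gap = 11) {
  ms <- lapply(records$sequence, mask_low_complexity,
               threshold = threshold, gap = gap)
  tibble::tibble(
    record_id = records$record_id,
    original = vapply(ms, `[[`, character(1), "original"),
    masked = vapply(ms, `[[`, character(1), "masked"),
    masked_fraction = vapply(ms, `[[`, numeric(1), "masked_fraction"))
}
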