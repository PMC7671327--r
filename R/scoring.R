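#' Alignment scoring parameters
#'
#' Bundles the substitution matrix and gap/statistics constants used by the
#' local aligner. Defaults are the standard gapped BLOSUM62 settings: gap
#' open 11, gap extend 1 (a gap of length L costs 11 + L), Karlin-Altschul
#' lambda = 0.267 and K = 0.041, and a significance cutoff of E < 0.05.
#'
#' @param matrix_name Name of a substitution matrix shipped with Biostrings
#'   (only `"BLOSUM62"` is used here).
#' @param gap_open,gap_extend Positive gap penalties, `gap_extend <= gap_open`.
#' @param karlin_lambda,karlin_K Positive Karlin-Altschul constants for the
#'   gapped score distribution.
#' @param e_value_cutoff Pairwise significance threshold (default 0.05).
#' @return A list of class `rf_scoring_params` with the matrix restricted to
#'   the 20 standard residues + X.
#' @export
scoring_params <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, karlin_lambda = 0.267,
                           karlin_K = 0.041, e_value_cutoff = 0.05) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            karlin_lambda > 0, karlin_K > 0, e_value_cutoff > 0)
  mat <- rf_submatrix(matrix_name)
  structure(list(matrix_name = matrix_name, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K,
                 e_value_cutoff = e_value_cutoff),
            class = "rf_scoring_params")
}

# Substitution matrix on the 20+X alphabet, taken from Biostrings' data.
rf_submatrix <- function(matrix_name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  full <- get(matrix_name, envir = env)
  full[RF_ALPHABET, RF_ALPHABET]
}

# Encode residue strings as 0-based integer codes into RF_ALPHABET.
encode_seq <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], RF_ALPHABET)
  if (anyNA(codes)) stop("sequence contains residues outside the 20+X alphabet")
  as.integer(codes - 1L)
}

rf_x_code <- function() match("X", RF_ALPHABET) - 1L
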