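# Shared constants and small helpers.

# Alphabet order of the Biostrings BLOSUM62 matrix; the C++ kernels index
# residues by position in this string. Unknown characters map to X.
.aa_alphabet <- "ARNDCQEGHILKMFPSTWYVBJZX*"

.blosum_cache <- new.env(parent = emptyenv())

#' Default scoring parameters
#'
#' BLOSUM62 with affine gap costs 11/1 (a gap of length k costs
#' `11 + k`) and gapped Karlin-Altschul constants `lambda = 0.267`,
#' `K = 0.041`, i.e. blastp defaults, so bit-scores are interpretable on
#' the usual scale.
#'
#' @param gap_open gap opening cost (positive).
#' @param gap_extend gap extension cost per residue (positive).
#' @param lambda,K gapped Karlin-Altschul parameters for the chosen
#'   matrix and gap costs.
#' @return list with the substitution matrix and statistics constants.
#' @export
score_params <- function(gap_open = 11L, gap_extend = 1L,
                         lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_extend > 0, lambda > 0, K > 0)
  list(matrix = .blosum62(), alphabet = .aa_alphabet,
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       lambda = lambda, K = K)
}

.blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    alpha <- strsplit(.aa_alphabet, "")[[1]]
    stopifnot(all(alpha %in% colnames(m)))
    .blosum_cache$m <- m[alpha, alpha]
  }
  .blosum_cache$m
}

# raw score -> bit score under Karlin-Altschul statistics
.bits_from_raw <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

# E-value of a single local hit: K * m * D * exp(-lambda * raw)
.hit_evalue <- function(raw, m, D, params) {
  params$K * m * D * exp(-params$lambda * raw)
}

.assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
}

# reverse each string in a character vector
.revstr <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}
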