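#' Scoring schemes for local and global alignment
#'
#' The pipeline aligns proteins with two scoring schemes, mirroring the tools
#' it replaces at desk scale: a BLAST-like local scheme (BLOSUM62, gap open
#' 11 / extend 1, Karlin-Altschul E-values with published gapped constants
#' lambda = 0.267, K = 0.041) and a needle-like global scheme (gap open 10 /
#' extend 0.5, terminal gaps free but counted in the alignment length).
#' A gap of length L costs `gap_open + L * gap_ext` under both schemes.
#'
#' E-values use the search space `m * N` (query length times total database
#' length) without finite-size length adjustment; at the 1e-10 cutoff used
#' throughout, the threshold behaviour matches BLAST closely enough that the
#' pipeline's decisions are driven by homology, not by the correction term.
#'
#' @param gap_open gap opening cost (positive).
#' @param gap_ext gap extension cost per residue (positive).
#' @param lambda,K Karlin-Altschul gapped parameters for the matrix/gap
#'   combination.
#' @param matrix substitution matrix name available in \pkg{Biostrings}
#'   (e.g. "BLOSUM62"), or an integer matrix with residue dimnames.
#' @param unknown how to treat residue symbols outside the matrix alphabet:
#'   `"reject"` (error) or `"wildcard"` (map to "X").
#' @return A list of class `"epc_scoring"`.
#' @export
local_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1,
                          lambda = 0.267, K = 0.041,
                          unknown = c("reject", "wildcard")) {
  unknown <- match.arg(unknown)
  sm <- resolve_matrix(matrix)
  structure(list(matrix = sm, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = lambda, K = K, unknown = unknown),
            class = "epc_scoring")
}

#' @rdname local_scoring
#' @export
global_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_ext = 0.5,
                           unknown = c("reject", "wildcard")) {
  unknown <- match.arg(unknown)
  sm <- resolve_matrix(matrix)
  structure(list(matrix = sm, gap_open = gap_open, gap_ext = gap_ext,
                 unknown = unknown),
            class = "epc_scoring")
}

resolve_matrix <- function(matrix) {
  if (is.matrix(matrix)) {
    stopifnot(!is.null(rownames(matrix)), identical(rownames(matrix), colnames(matrix)))
    storage.mode(matrix) <- "integer"
    return(matrix)
  }
  env <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = env)
  sm <- get(matrix, envir = env)
  storage.mode(sm) <- "integer"
  sm
}

#' The 20 standard amino acids
#' @export
aa_alphabet <- function() strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Encode character/AAStringSet sequences as 0-based integer codes into the
# scoring matrix alphabet. Returns a list of integer vectors.
encode_seqs <- function(seqs, scoring) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (methods::is(seqs, "XString")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("sequences must be character or AAStringSet")
  alph <- rownames(scoring$matrix)
  lapply(seqs, function(s) {
    codes <- match(strsplit(s, "")[[1]], alph)
    if (anyNA(codes)) {
      if (scoring$unknown == "reject")
        stop("unknown residue symbol(s): ",
             paste(unique(strsplit(s, "")[[1]][is.na(codes)]), collapse = ", "))
      codes[is.na(codes)] <- match("X", alph)
    }
    as.integer(codes - 1L)
  })
}

#' Karlin-Altschul bit score and E-value
#'
#' @param score raw alignment score.
#' @param m query length in residues.
#' @param N total database length in residues.
#' @param scoring a [local_scoring()] scheme carrying `lambda` and `K`.
#' @return Numeric vector (vectorised over `score`/`m`).
#' @export
ka_bitscore <- function(score, scoring = local_scoring()) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' @rdname ka_bitscore
#' @export
ka_evalue <- function(score, m, N, scoring = local_scoring()) {
  m * N * 2^(-ka_bitscore(score, scoring))
}

# smallest raw score that could pass the E-value cutoff for any query of
# length >= m_min against a database of N residues (conservative lower bound)
min_passing_score <- function(evalue_max, m_min, N, scoring) {
  s <- (log(m_min * N / evalue_max) + log(scoring$K)) / scoring$lambda
  if (!is.finite(s) || s < 1) return(1L)
  as.integer(floor(s))
}
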