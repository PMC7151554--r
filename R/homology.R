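#' Optimal local search of a query against a sequence database
#'
#' Exact affine-gap Smith-Waterman of one protein query against every
#' database sequence, reported BLAST-style: one hit per database sequence
#' whose optimal local alignment passes the E-value cutoff, sorted by
#' ascending E-value, ties broken by descending bit score and then
#' lexicographic subject id.
#'
#' @param query a single protein sequence (character or `AAString`).
#' @param database named character vector or `AAStringSet`.
#' @param scoring a [local_scoring()] scheme.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @param query_id id used in the `query` column.
#' @return A hit table: `data.frame(query, subject, score, bitscore, evalue,
#'   pident_local, qcov)`. `pident_local` is percent identity over the local
#'   alignment columns; `qcov` the percent of the query covered by it.
#' @export
local_search <- function(query, database, scoring = local_scoring(),
                         evalue_max = 1e-10, query_id = "query") {
  if (methods::is(query, "XString") || methods::is(query, "XStringSet"))
    query <- as.character(query)
  if (length(query) != 1L || is.na(query) || nchar(query) == 0L)
    stop("query must be a single nonempty sequence")
  if (methods::is(database, "XStringSet")) database <- as.character(database)
  if (length(database) == 0L) stop("database is empty")
  if (is.null(names(database)))
    names(database) <- paste0("db", seq_along(database))
  enc <- encode_seqs(c(query, unname(database)), scoring)
  lens <- lengths(enc)
  N <- sum(lens[-1])
  minraw <- min_passing_score(evalue_max, lens[1], N, scoring)
  pairs <- cpp_pair_scores(enc, 1L, seq_along(database) + 1L, FALSE,
                           scoring$matrix, scoring$gap_open, scoring$gap_ext,
                           minraw)
  hits <- directed_hits(pairs, enc, lens, scoring, evalue_max,
                        n_query = N, n_subject = N,
                        ids = c(query_id, names(database)),
                        directions = "forward")
  sort_hits(hits)
}

#' Percent global identity of two sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under needle-like defaults
#' (gap open 10 / extend 0.5, terminal gaps free), reporting
#' `100 * identical positions / alignment length` with gap columns --
#' including terminal ones -- in the denominator.
#'
#' @param seq_a,seq_b protein sequences (character or `AAString`).
#' @param scoring a [global_scoring()] scheme.
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(seq_a, seq_b, scoring = global_scoring()) {
  enc <- encode_seqs(c(as.character(seq_a), as.character(seq_b)), scoring)
  if (any(lengths(enc) == 0L)) stop("sequences must be nonempty")
  cpp_nw_stats(enc[[1]], enc[[2]], scoring$matrix,
               scoring$gap_open, scoring$gap_ext)[1]
}

#' All-vs-all local hits within one sequence set
#'
#' Directed hit table over all ordered pairs in `seqs` whose optimal local
#' alignment passes the E-value cutoff. The search space for each direction
#' is query length times total residues in the set.
#'
#' @param seqs named character vector or `AAStringSet`.
#' @inheritParams local_search
#' @return A hit table as in [local_search()], both directions included.
#' @export
all_vs_all_hits <- function(seqs, scoring = local_scoring(),
                            evalue_max = 1e-10) {
  seqs <- as_named_character(seqs)
  enc <- encode_seqs(unname(seqs), scoring)
  lens <- lengths(enc)
  if (any(lens == 0L)) stop("empty sequence in input")
  N <- sum(lens)
  minraw <- min_passing_score(evalue_max, min(lens), N, scoring)
  pairs <- cpp_pair_scores(enc, seq_along(enc), integer(0), TRUE,
                           scoring$matrix, scoring$gap_open, scoring$gap_ext,
                           minraw)
  sort_hits(directed_hits(pairs, enc, lens, scoring, evalue_max,
                          n_query = N, n_subject = N, ids = names(seqs),
                          directions = "both"))
}

#' Local hits between two sequence sets
#'
#' Directed hits in both directions between `query_set` and `subject_set`
#' (e.g. all eukaryote vs all prokaryote sequences). E-values use the
#' residues of the searched set as database size.
#'
#' @param query_set,subject_set named character vectors or `AAStringSet`s.
#' @inheritParams local_search
#' @return A hit table as in [local_search()].
#' @export
cross_hits <- function(query_set, subject_set, scoring = local_scoring(),
                       evalue_max = 1e-10) {
  query_set <- as_named_character(query_set)
  subject_set <- as_named_character(subject_set)
  enc <- encode_seqs(c(unname(query_set), unname(subject_set)), scoring)
  lens <- lengths(enc)
  if (any(lens == 0L)) stop("empty sequence in input")
  nq <- length(query_set)
  Nq <- sum(lens[seq_len(nq)])
  Ns <- sum(lens[-seq_len(nq)])
  minraw <- min_passing_score(evalue_max, min(lens), max(Nq, Ns), scoring)
  pairs <- cpp_pair_scores(enc, seq_len(nq), nq + seq_along(subject_set),
                           FALSE, scoring$matrix, scoring$gap_open,
                           scoring$gap_ext, minraw)
  sort_hits(directed_hits(pairs, enc, lens, scoring, evalue_max,
                          n_query = Nq, n_subject = Ns,
                          ids = c(names(query_set), names(subject_set)),
                          directions = "both"))
}

# Expand symmetric pair scores into directed hit rows passing the cutoff.
# n_query: database size used for reverse (subject->query) E-values;
# n_subject: database size for forward (query->subject) E-values.
directed_hits <- function(pairs, enc, lens, scoring, evalue_max,
                          n_query, n_subject, ids,
                          directions = c("both", "forward")) {
  directions <- match.arg(directions)
  empty <- data.frame(query = character(0), subject = character(0),
                      score = integer(0), bitscore = numeric(0),
                      evalue = numeric(0), pident_local = numeric(0),
                      qcov = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  qi <- pairs$qi; si <- pairs$si; sc <- pairs$score
  keep_self <- qi != si
  qi <- qi[keep_self]; si <- si[keep_self]; sc <- sc[keep_self]
  if (length(qi) == 0L) return(empty)
  e_fwd <- ka_evalue(sc, lens[qi], n_subject, scoring)
  e_rev <- ka_evalue(sc, lens[si], n_query, scoring)
  keep <- e_fwd <= evalue_max |
    (directions == "both" & e_rev <= evalue_max)
  if (!any(keep)) return(empty)
  qi <- qi[keep]; si <- si[keep]; sc <- sc[keep]
  e_fwd <- e_fwd[keep]; e_rev <- e_rev[keep]
  stats <- cpp_sw_stats_batch(enc, qi, si, scoring$matrix,
                              scoring$gap_open, scoring$gap_ext)
  pident <- ifelse(stats[, 3] > 0, 100 * stats[, 2] / stats[, 3], 0)
  cov_q <- 100 * (stats[, 5] - stats[, 4] + 1) / lens[qi]
  cov_s <- 100 * (stats[, 7] - stats[, 6] + 1) / lens[si]
  bits <- ka_bitscore(sc, scoring)
  fwd <- data.frame(query = ids[qi], subject = ids[si], score = sc,
                    bitscore = bits, evalue = e_fwd, pident_local = pident,
                    qcov = cov_q, stringsAsFactors = FALSE)
  fwd <- fwd[e_fwd <= evalue_max, , drop = FALSE]
  if (directions == "forward") return(fwd)
  rev <- data.frame(query = ids[si], subject = ids[qi], score = sc,
                    bitscore = bits, evalue = e_rev, pident_local = pident,
                    qcov = cov_s, stringsAsFactors = FALSE)
  rev <- rev[e_rev <= evalue_max, , drop = FALSE]
  rbind(fwd, rev)
}

sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

as_named_character <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs
}

#' Reciprocal best hits with a global-identity gate
#'
#' Computes reciprocal best hits from a directed hit table. The best hit of
#' a query is taken per target genome (`scope = "per_genome"`, the
#' convention of rBBH-based family clustering: every query has one best hit
#' in every other genome), or over the whole set (`scope = "global"`).
#' Within a key the hit order is ascending E-value, descending bit score,
#' lexicographic subject id. Same-genome pairs and self hits are excluded.
#' Each reciprocal pair is annotated with its global percent identity and
#' retained only if it passes `min_global_identity` (25 for prokaryotic
#' domains, 40 for eukaryotes).
#'
#' @param hits directed hit table from [all_vs_all_hits()].
#' @param seqs the sequences the hits refer to (named, for identity).
#' @param genome_map named character vector: sequence id -> genome id.
#' @param min_global_identity retention cutoff in percent.
#' @param scoring a [global_scoring()] scheme for the identity annotation.
#' @param scope best-hit scope (see above).
#' @return `data.frame(id_a, id_b, global_identity)` with `id_a < id_b`,
#'   each unordered pair stored once.
#' @export
reciprocal_best_hits <- function(hits, seqs, genome_map,
                                 min_global_identity = 25,
                                 scoring = global_scoring(),
                                 scope = c("per_genome", "global")) {
  scope <- match.arg(scope)
  seqs <- as_named_character(seqs)
  missing_ids <- setdiff(unique(c(hits$query, hits$subject)), names(genome_map))
  if (length(missing_ids) > 0L)
    stop("hit table references sequences outside the id set: ",
         paste(head(missing_ids, 3), collapse = ", "))
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      global_identity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  h <- hits[hits$query != hits$subject, , drop = FALSE]
  h <- h[genome_map[h$query] != genome_map[h$subject], , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  key <- if (scope == "per_genome")
    paste(h$query, genome_map[h$subject], sep = "\r") else h$query
  ord <- order(key, h$evalue, -h$bitscore, h$subject)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(if (scope == "per_genome")
    paste(h$query, genome_map[h$subject], sep = "\r") else h$query), ,
    drop = FALSE]
  bkey <- paste(best$query, best$subject, sep = "\r")
  rkey <- paste(best$subject, best$query, sep = "\r")
  mutual <- best[rkey %in% bkey, , drop = FALSE]
  if (nrow(mutual) == 0L) return(empty)
  a <- pmin(mutual$query, mutual$subject)
  b <- pmax(mutual$query, mutual$subject)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[keep]; b <- b[keep]
  enc <- encode_seqs(unname(seqs), scoring)
  idx <- stats::setNames(seq_along(seqs), names(seqs))
  gi <- cpp_nw_identity_batch(enc, idx[a], idx[b], scoring$matrix,
                              scoring$gap_open, scoring$gap_ext)[, "identity"]
  out <- data.frame(id_a = a, id_b = b, global_identity = gi,
                    stringsAsFactors = FALSE)
  out <- out[out$global_identity >= min_global_identity, , drop = FALSE]
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
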