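# Independent dynamic-programming oracles and brute-force enumerations used
# to pin down the alignment and clustering primitives. Scoring conventions
# (gap of length L costs open + L*ext; global alignment has free but counted
# terminal gaps; traceback prefers diagonal, then gap-in-subject, then
# gap-in-query) are the package's documented conventions, restated here in
# plain R.

oracle_scoring_matrix <- function() {
  sc <- local_scoring()
  sc$matrix
}

# full-matrix affine Smith-Waterman score
oracle_sw_score <- function(a, b, sm, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  GO <- gap_open + gap_ext
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - GO)
      F[i, j] <- max(F[i - 1, j] - gap_ext, H[i - 1, j] - GO)
      H[i, j] <- max(0, H[i - 1, j - 1] + sm[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# full-matrix affine global alignment with free terminal gaps; returns
# score and percent identity over the full alignment length
oracle_nw <- function(a, b, sm, gap_open, gap_ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  GO <- gap_open + gap_ext
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in query (left moves)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in subject (up moves)
  Bst <- matrix(0, n + 1, m + 1)
  Bst[1, ] <- 0; Bst[, 1] <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      M[i, j] <- Bst[i - 1, j - 1] + sm[A[i - 1], B[j - 1]]
      X[i, j] <- max(X[i, j - 1] - gap_ext, max(M[i, j - 1], Y[i, j - 1]) - GO)
      Y[i, j] <- max(Y[i - 1, j] - gap_ext, max(M[i - 1, j], X[i - 1, j]) - GO)
      Bst[i, j] <- max(M[i, j], X[i, j], Y[i, j])
    }
  }
  best <- -Inf; bi <- n; bj <- m
  for (j in (m + 1):1) {        # last row, scanning j = m..0
    v <- Bst[n + 1, j]
    if (v > best) { best <- v; bi <- n; bj <- j - 1 }
  }
  for (i in (n + 1):1) {        # last column, scanning i = n..0
    v <- Bst[i, m + 1]
    if (v > best) { best <- v; bi <- i - 1; bj <- m }
  }
  cols <- (n - bi) + (m - bj)
  nid <- 0
  i <- bi; j <- bj
  state <- -1
  while (i > 0 && j > 0) {
    if (state == -1) {
      state <- if (Bst[i + 1, j + 1] == M[i + 1, j + 1]) 0
        else if (Bst[i + 1, j + 1] == Y[i + 1, j + 1]) 1 else 2
    }
    if (state == 0) {
      if (A[i] == B[j]) nid <- nid + 1
      cols <- cols + 1; i <- i - 1; j <- j - 1
      state <- -1
    } else if (state == 1) {
      cols <- cols + 1
      v <- Y[i + 1, j + 1]
      i <- i - 1
      state <- if (v == Y[i + 1, j + 1] - gap_ext) 1
        else if (v == M[i + 1, j + 1] - GO) 0 else 2
      if (i == 0 || j == 0) state <- -1
    } else {
      cols <- cols + 1
      v <- X[i + 1, j + 1]
      j <- j - 1
      state <- if (v == X[i + 1, j + 1] - gap_ext) 2
        else if (v == M[i + 1, j + 1] - GO) 0 else 1
      if (i == 0 || j == 0) state <- -1
    }
  }
  cols <- cols + i + j
  list(score = best, identity = if (cols > 0) 100 * nid / cols else 0,
       align_cols = cols)
}

# brute-force reciprocal best hits from a directed hit table: per query and
# target genome, enumerate every hit and keep the best under the stated
# order; report mutual pairs
oracle_rbh_pairs <- function(hits, genome_map) {
  best_of <- function(q, g) {
    cand <- hits[hits$query == q & genome_map[hits$subject] == g &
                 hits$subject != q & genome_map[hits$subject] !=
                 genome_map[q], , drop = FALSE]
    if (nrow(cand) == 0) return(NA_character_)
    bst <- cand[1, ]
    for (r in seq_len(nrow(cand))) {
      x <- cand[r, ]
      if (x$evalue < bst$evalue ||
          (x$evalue == bst$evalue && x$bitscore > bst$bitscore) ||
          (x$evalue == bst$evalue && x$bitscore == bst$bitscore &&
           x$subject < bst$subject)) bst <- x
    }
    bst$subject
  }
  ids <- unique(c(hits$query, hits$subject))
  pairs <- character(0)
  for (q in ids) {
    for (g in unique(genome_map[ids])) {
      b <- best_of(q, g)
      if (is.na(b)) next
      back <- best_of(b, genome_map[[q]])
      if (!is.na(back) && back == q) {
        key <- paste(min(q, b), max(q, b), sep = "|")
        pairs <- union(pairs, key)
      }
    }
  }
  sort(pairs)
}

# reference Markov clustering via the bundled numpy implementation
oracle_mcl <- function(nodes, edges, inflation = 2, prune = 1e-5,
                       max_iter = 200, tol = 1e-6) {
  script <- system.file("oracles", "mcl_reference.py",
                        package = "epcAncestry")
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(
    list(nodes = nodes,
         edges = if (nrow(edges) > 0)
           lapply(seq_len(nrow(edges)), function(k)
             list(edges$id_a[k], edges$id_b[k], edges$weight[k]))
         else list(),
         inflation = inflation, prune = prune, max_iter = max_iter,
         tol = tol),
    fin, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, fin, fout))
  stopifnot(status == 0)
  out <- jsonlite::read_json(fout, simplifyVector = TRUE)
  cl <- out$clusters
  if (is.matrix(cl)) cl <- split(cl, row(cl))
  unname(lapply(cl, sort))
}

# canonical form of a partition: sorted list of sorted member vectors
partition_groups <- function(assignment) {
  unname(lapply(
    split(names(assignment), assignment)[order(vapply(
      split(names(assignment), assignment), min, character(1)))],
    sort))
}

random_protein <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}
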