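sc_local <- local_scoring()
sc_global <- global_scoring()

test_that("local alignment scores equal the exhaustive DP oracle", {
  set.seed(101)
  sm <- oracle_scoring_matrix()
  for (k in 1:50) {
    la <- sample(8:45, 1); lb <- sample(8:45, 1)
    if (k %% 2 == 0) {
      anc <- random_protein(max(la, lb))
      a <- substr(mutate_sequence(anc, sample(45:95, 1)), 1, la)
      b <- substr(mutate_sequence(anc, sample(45:95, 1)), 1, lb)
    } else {
      a <- random_protein(la); b <- random_protein(lb)
    }
    hit <- local_search(a, c(db1 = b), sc_local, evalue_max = 1e12)
    got <- if (nrow(hit) == 0) 0 else hit$score[1]
    expect_equal(got,
                 oracle_sw_score(a, b, sm, sc_local$gap_open,
                                 sc_local$gap_ext),
                 ignore_attr = TRUE)
  }
})

test_that("global identity matches the DP oracle and needle conventions", {
  set.seed(202)
  sm <- oracle_scoring_matrix()
  for (k in 1:50) {
    la <- sample(6:40, 1); lb <- sample(6:40, 1)
    if (k %% 2 == 0) {
      anc <- random_protein(max(la, lb))
      a <- substr(mutate_sequence(anc, 70), 1, la)
      b <- substr(mutate_sequence(anc, 70), 1, lb)
    } else {
      a <- random_protein(la); b <- random_protein(lb)
    }
    expect_equal(global_identity(a, b, sc_global),
                 oracle_nw(a, b, sm, sc_global$gap_open,
                           sc_global$gap_ext)$identity,
                 tolerance = 1e-12)
  }
  # terminal gaps are counted in the denominator
  expect_equal(global_identity("AAAA", "AAAACCCC"), 50)
  # symmetry and the identity case
  s1 <- random_protein(30); s2 <- random_protein(30)
  expect_equal(global_identity(s1, s2), global_identity(s2, s1))
  expect_equal(global_identity(s1, s1), 100)
  expect_error(global_identity("", "AAA"), "nonempty")
})

test_that("local_search reports sorted, gated, well-formed hits", {
  set.seed(303)
  target <- random_protein(200)
  db <- c(match = target,
          rel = mutate_sequence(target, 60),
          junk1 = random_protein(180),
          junk2 = random_protein(150))
  hits <- local_search(target, db, sc_local, evalue_max = 1e-10)
  expect_identical(hits$subject[1], "match")
  expect_equal(hits$pident_local[1], 100)
  expect_equal(hits$qcov[1], 100)
  expect_true(all(diff(hits$evalue) >= 0))
  expect_true(all(hits$evalue <= 1e-10))
  expect_false(any(c("junk1", "junk2") %in% hits$subject))
  # unrelated database under the strict cutoff: empty
  empty <- local_search(random_protein(100),
                        c(a = random_protein(100), b = random_protein(90)),
                        sc_local, evalue_max = 1e-10)
  expect_equal(nrow(empty), 0)
  expect_error(local_search("", db), "nonempty")
})

test_that("E-values are monotone decreasing in score for fixed lengths", {
  e <- ka_evalue(seq(50, 300, by = 10), m = 150, N = 1e5, sc_local)
  expect_true(all(diff(e) < 0))
  expect_true(all(e >= 0))
})

test_that("unknown residues are rejected or mapped to the wildcard", {
  expect_error(global_identity("AOOB", "AB",
                               global_scoring(unknown = "reject")),
               "unknown residue")
  wc <- global_scoring(unknown = "wildcard")
  expect_true(global_identity("ACDEFGHIK", "ACDEFGHIK", wc) == 100)
  expect_no_error(global_identity("ACDEFGHIKU", "ACDEFGHIK", wc))
})

test_that("reciprocal best hits equal brute-force enumeration", {
  set.seed(404)
  for (inst in 1:6) {
    n_genomes <- sample(3:5, 1)
    n_fams <- sample(2:4, 1)
    seqs <- character(0); gmap <- character(0)
    ancs <- replicate(n_fams, random_protein(sample(60:90, 1)))
    for (g in seq_len(n_genomes)) {
      for (f in seq_len(n_fams)) {
        if (runif(1) < 0.75) {
          id <- sprintf("g%d_f%d", g, f)
          seqs[id] <- mutate_sequence(ancs[f], 85)
          gmap[id] <- sprintf("G%d", g)
        }
      }
    }
    if (length(seqs) < 4 || length(seqs) > 25) next
    hits <- all_vs_all_hits(seqs, sc_local, evalue_max = 1e-5)
    got <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 0)
    got_keys <- sort(paste(got$id_a, got$id_b, sep = "|"))
    expect_identical(got_keys, oracle_rbh_pairs(hits, gmap))
    # matching property per genome pair: a sequence pairs at most once
    # with any given partner genome
    if (nrow(got) > 0) {
      keys <- c(paste(got$id_a, gmap[got$id_b]),
                paste(got$id_b, gmap[got$id_a]))
      expect_false(any(duplicated(keys)))
    }
  }
})

test_that("broken reciprocity yields no pair; forced reciprocity one", {
  gmap <- c(a = "G1", b = "G2", c = "G3")
  base <- data.frame(score = 100L, bitscore = 30, evalue = 1e-20,
                     pident_local = 90, qcov = 90)
  # a's best is b, b's best is c, c's best is b
  hits <- rbind(cbind(data.frame(query = "a", subject = "b"), base),
                cbind(data.frame(query = "b", subject = "c"), base),
                cbind(data.frame(query = "c", subject = "b"), base))
  seqs <- c(a = "ACDEFGHIKLMNPQRSTVWY", b = "ACDEFGHIKLMNPQRSTVWY",
            c = "ACDEFGHIKLMNPQRSTVWY")
  # per-genome scope: b<->c are mutual best within their genomes; a->b is
  # not reciprocated (b has no hit back to genome G1)
  got <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 0)
  expect_identical(got$id_a, "b")
  expect_identical(got$id_b, "c")
  expect_false("a" %in% c(got$id_a, got$id_b))
  # two sequences that are each other's only hits: one pair
  h2 <- rbind(cbind(data.frame(query = "a", subject = "b"), base),
              cbind(data.frame(query = "b", subject = "a"), base))
  got2 <- reciprocal_best_hits(h2, seqs[c("a", "b")], gmap,
                               min_global_identity = 0)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$global_identity, 100)
})

test_that("the global-identity gate drops low-identity reciprocal pairs", {
  set.seed(505)
  a <- random_protein(80)
  b <- mutate_sequence(a, 50)   # ~50% identity
  gmap <- c(x = "G1", y = "G2")
  seqs <- c(x = a, y = b)
  hits <- all_vs_all_hits(seqs, sc_local, evalue_max = 1)
  kept <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 25)
  dropped <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 90)
  expect_equal(nrow(kept), 1)
  expect_equal(nrow(dropped), 0)
})

test_that("global best-hit scope differs from per-genome scope as documented", {
  gmap <- c(a = "G1", b = "G2", x = "G3", y = "G3")
  base <- data.frame(score = 100L, bitscore = 30, pident_local = 90,
                     qcov = 90)
  hits <- rbind(
    cbind(data.frame(query = "a", subject = "b", evalue = 1e-20), base),
    cbind(data.frame(query = "b", subject = "a", evalue = 1e-20), base),
    cbind(data.frame(query = "a", subject = "x", evalue = 1e-40), base),
    cbind(data.frame(query = "x", subject = "y", evalue = 1e-50), base))
  seqs <- stats::setNames(rep("ACDEFGHIKLMNPQRSTVWY", 4), names(gmap))
  pg <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 0,
                             scope = "per_genome")
  expect_true(any(pg$id_a == "a" & pg$id_b == "b"))
  gl <- reciprocal_best_hits(hits, seqs, gmap, min_global_identity = 0,
                             scope = "global")
  # a's single global best is x, which prefers y: reciprocity broken
  expect_false(any(gl$id_a == "a" | gl$id_b == "a"))
})
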