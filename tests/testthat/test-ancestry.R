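test_that("genus quotas follow proportional largest-remainder allocation", {
  gt <- data.frame(genome_id = sprintf("b%03d", 1:200),
                   genus = rep(c("gA", "gB", "gC"), c(100, 60, 40)),
                   stringsAsFactors = FALSE)
  sch <- downsample_scheme(5, 100, gt, seed = 3)
  draw <- draw_bacterial_subsample(sch, 1)
  tab <- table(gt$genus[match(draw, gt$genome_id)])
  expect_equal(unname(tab[["gA"]]), 50)   # a genus holding 50% gives 50
  expect_equal(unname(tab[["gB"]]), 30)
  expect_equal(unname(tab[["gC"]]), 20)
  # remainder case: sizes 5/3/2, sample 5 -> quotas 3/1/1 (tie to larger)
  gt2 <- data.frame(genome_id = sprintf("c%02d", 1:10),
                    genus = rep(c("gA", "gB", "gC"), c(5, 3, 2)),
                    stringsAsFactors = FALSE)
  d2 <- draw_bacterial_subsample(downsample_scheme(2, 5, gt2, seed = 4), 1)
  t2 <- table(gt2$genus[match(d2, gt2$genome_id)])
  expect_equal(as.integer(t2[c("gA", "gB", "gC")]), c(3L, 1L, 1L))
})

test_that("an exhaustive draw returns the whole population, any seed", {
  gt <- data.frame(genome_id = sprintf("b%02d", 1:12),
                   genus = rep(c("g1", "g2"), c(7, 5)))
  for (sd in c(1, 99)) {
    sch <- downsample_scheme(3, 12, gt, seed = sd)
    expect_identical(draw_bacterial_subsample(sch, 2), sort(gt$genome_id))
  }
})

test_that("degenerate scheme inputs error", {
  gt <- data.frame(genome_id = c("b1", "b2"), genus = "g")
  expect_error(downsample_scheme(10, 0, gt), "sample_size")
  expect_error(downsample_scheme(10, 3, gt), "exceeds")
  expect_error(downsample_scheme(0, 1, gt), "n_replicates")
  sch <- downsample_scheme(2, 1, gt)
  expect_error(draw_bacterial_subsample(sch, 3), "out of range")
})

test_that("draws are deterministic in (seed, replicate) and differ across replicates", {
  gt <- data.frame(genome_id = sprintf("b%02d", 1:30),
                   genus = rep(c("g1", "g2", "g3"), 10))
  s1 <- downsample_scheme(20, 10, gt, seed = 5)
  s2 <- downsample_scheme(20, 10, gt, seed = 5)
  expect_identical(draw_bacterial_subsample(s1, 7),
                   draw_bacterial_subsample(s2, 7))
  draws <- vapply(1:20, function(i)
    paste(draw_bacterial_subsample(s1, i), collapse = ","), character(1))
  expect_gt(length(unique(draws)), 1)
})

test_that("replicate scoring counts each EPC once per genome", {
  es <- make_epcs(
    origins = c("bacterial", "bacterial", "bacterial", "archaeal"),
    prok_members = list(c("b1", "b2"), "b3", "b1", "a1"),
    euk_members = list("E1", "E1", "E1", "E1"))
  sc <- score_replicate(es, c("b1", "b2", "b3"), "a1")
  expect_equal(sc$bacterial[sc$genome_id == "E1"], 3)
  expect_equal(sc$archaeal[sc$genome_id == "E1"], 1)
  # a bacterial EPC whose prokaryotes all miss the sample contributes 0
  sc2 <- score_replicate(es, "b2", "a1")
  expect_equal(sc2$bacterial[sc2$genome_id == "E1"], 1)
  # dual/ambiguous input is rejected
  bad <- make_epcs("dual", list("b1"), list("E1"))
  expect_error(score_replicate(bad, "b1", "a1"), "non-exclusive")
})

test_that("with the full population the estimator equals direct counting", {
  sim <- simulate_dataset(simulation_config(
    n_bacteria = 10, n_archaea = 8, n_eukaryotes = 5,
    genus_sizes = c(6, 4),
    n_families = c(euk_bact = 12, euk_arch = 8),
    seq_length_range = c(60, 80), seed = 41))
  es <- epcs_from_truth(sim)
  gt <- sim$genomes[sim$genomes$domain == "bacteria",
                    c("genome_id", "genus")]
  arch <- sim$genomes$genome_id[sim$genomes$domain == "archaea"]
  euks <- sim$genomes$genome_id[sim$genomes$domain == "eukaryote"]
  sch <- downsample_scheme(25, nrow(gt), gt, seed = 6)
  est <- estimate_proportions(es, sch, arch, euks)
  dc <- direct_counts(es, gt$genome_id, arch, euks)
  expect_equal(est$mean_bacterial, dc$mean_bacterial)
  expect_equal(est$mean_archaeal, dc$mean_archaeal)
  expect_equal(est$p_bacterial, dc$p_bacterial)
  expect_true(all(est$sd_bacterial == 0))
})

test_that("estimates are invariant to EPC order and reproducible by seed", {
  es <- make_epcs(
    origins = c("bacterial", "archaeal", "bacterial", "bacterial"),
    prok_members = list("b1", "a1", c("b2", "b3"), "b4"),
    euk_members = list(c("E1", "E2"), "E1", "E2", c("E1", "E2")))
  gt <- data.frame(genome_id = sprintf("b%d", 1:4),
                   genus = c("g1", "g1", "g2", "g2"))
  sch <- downsample_scheme(40, 2, gt, seed = 8)
  est1 <- estimate_proportions(es, sch, "a1")
  est2 <- estimate_proportions(es, sch, "a1")
  expect_identical(est1, est2)
  perm <- c(3, 1, 4, 2)
  es_perm <- epcAncestry:::new_epc_set(es$epcs[perm, ],
                                       presence = es$presence)
  est3 <- estimate_proportions(es_perm, sch, "a1")
  expect_equal(est1$mean_bacterial, est3$mean_bacterial)
  expect_equal(est1$p_bacterial, est3$p_bacterial)
})

test_that("zero-total genomes are flagged with undefined proportions", {
  es <- make_epcs("bacterial", list("b1"), list("E1"))
  gt <- data.frame(genome_id = "b1", genus = "g")
  sch <- downsample_scheme(5, 1, gt, seed = 2)
  est <- estimate_proportions(es, sch, character(0),
                              euk_genomes = c("E1", "E2"))
  expect_true(est$zero_total[est$genome_id == "E2"])
  expect_true(is.na(est$p_bacterial[est$genome_id == "E2"]))
  expect_equal(est$p_bacterial[est$genome_id == "E1"], 1)
})

test_that("group summary averages per-genome proportions", {
  est <- data.frame(genome_id = c("E1", "E2", "E3"),
                    mean_bacterial = c(6, 7, 2), mean_archaeal = c(4, 3, 8),
                    sd_bacterial = 0,
                    p_bacterial = c(0.6, 0.7, 0.2),
                    p_archaeal = c(0.4, 0.3, 0.8),
                    zero_total = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(genome_id = c("E1", "E2", "E3"),
                     group = c("Opisthokonta", "Opisthokonta",
                               "Archaeplastida"),
                     plastid = c(FALSE, FALSE, TRUE),
                     parasite = c(FALSE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  gs <- group_summary(est, meta)
  expect_equal(gs$p_bacterial[gs$group == "Opisthokonta"], 0.65)
  expect_equal(gs$p_bacterial[gs$group == "Archaeplastida"], 0.2)
  expect_equal(gs$p_bacterial[gs$group == "All eukaryotes"], 0.5)
  expect_equal(gs$p_bacterial[gs$group == "Parasites"], 0.7)
  expect_equal(gs$p_archaeal + gs$p_bacterial, rep(1, nrow(gs)))
})

test_that("size correlation matches the closed-form Pearson computation", {
  est <- data.frame(genome_id = sprintf("E%d", 1:5),
                    mean_bacterial = c(10, 14, 9, 20, 13),
                    mean_archaeal = c(8, 6, 12, 9, 7),
                    sd_bacterial = 0,
                    p_bacterial = 0.5, p_archaeal = 0.5, zero_total = FALSE)
  sizes <- stats::setNames(c(1000, 1500, 900, 2100, 1200), est$genome_id)
  r2 <- size_correlation(est, sizes)
  pearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    (num / den)^2
  }
  expect_equal(unname(r2["r2_bacterial"]),
               pearson(est$mean_bacterial, sizes))
  expect_equal(unname(r2["r2_archaeal"]),
               pearson(est$mean_archaeal, sizes))
  # counts exactly proportional to size: r2 = 1
  est2 <- est
  est2$mean_bacterial <- sizes / 100
  expect_equal(unname(size_correlation(est2, sizes)["r2_bacterial"]), 1)
  expect_error(size_correlation(est, sizes * 0 + 5), "constant")
})

test_that("ratio-of-means and mean-of-ratios agree when counts are stable", {
  es <- make_epcs(
    origins = c("bacterial", "archaeal"),
    prok_members = list(c("b1", "b2"), "a1"),
    euk_members = list(c("E1", "E2"), c("E1", "E2")))
  gt <- data.frame(genome_id = c("b1", "b2"), genus = "g")
  sch <- downsample_scheme(10, 2, gt, seed = 12)  # exhaustive draws
  rm_ <- estimate_proportions(es, sch, "a1")
  mr <- estimate_proportions(es, sch, "a1", mode = "mean_of_ratios")
  expect_equal(rm_$p_bacterial, mr$p_bacterial)
  expect_equal(rm_$p_bacterial, c(0.5, 0.5))
})
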