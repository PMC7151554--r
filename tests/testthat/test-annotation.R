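ref_fixture <- function(seed = 51) {
  set.seed(seed)
  refs <- stats::setNames(vapply(1:5, function(i) random_protein(120),
                                 character(1)),
                          sprintf("ref%d", 1:5))
  annotation_reference(
    refs,
    data.frame(seq_id = names(refs),
               function_id = sprintf("K%05d", 1:5),
               category = c("metabolism", "information", "cellular",
                            "environmental", "organismal"),
               stringsAsFactors = FALSE))
}

test_that("best-hit annotation obeys E-value and coverage gates", {
  ref <- ref_fixture()
  member_exact <- ref$sequences[["ref2"]]
  member_rel <- mutate_sequence(ref$sequences[["ref1"]], 70)
  # covers only ~55% of its own length: coverage gate fails
  member_partial <- paste0(substr(ref$sequences[["ref3"]], 1, 55),
                           random_protein(45))
  member_junk <- random_protein(100)
  members <- c(m1 = member_exact, m2 = member_rel, m3 = member_partial,
               m4 = member_junk)
  ann <- annotate_proteins(members, ref)
  expect_equal(ann$function_id[ann$seq_id == "m1"], "K00002")
  expect_equal(ann$category[ann$seq_id == "m1"], "information")
  expect_equal(ann$function_id[ann$seq_id == "m2"], "K00001")
  expect_true(is.na(ann$function_id[ann$seq_id == "m3"]))
  expect_true(is.na(ann$function_id[ann$seq_id == "m4"]))
})

test_that("assignments equal a brute-force best-hit enumeration", {
  ref <- ref_fixture(52)
  set.seed(99)
  members <- stats::setNames(
    vapply(sample(names(ref$sequences), 8, replace = TRUE),
           function(r) mutate_sequence(ref$sequences[[r]], 75),
           character(1)),
    sprintf("m%d", 1:8))
  ann <- annotate_proteins(members, ref)
  for (m in names(members)) {
    # enumerate every reference entry separately, keep the best by the
    # stated order, apply both gates
    rows <- do.call(rbind, lapply(names(ref$sequences), function(r)
      local_search(members[[m]], ref$sequences[r], evalue_max = Inf,
                   query_id = m)))
    rows <- rows[rows$evalue <= 1e-10 & rows$qcov >= 80, , drop = FALSE]
    expected <- if (nrow(rows) == 0) NA_character_ else {
      rows <- rows[order(rows$evalue, -rows$bitscore, rows$subject), ]
      ref$labels$function_id[match(rows$subject[1], ref$labels$seq_id)]
    }
    expect_identical(ann$function_id[ann$seq_id == m], expected)
  }
})

test_that("majority rule ignores unannotated members and flags ties", {
  asg <- data.frame(seq_id = sprintf("s%d", 1:6),
                    function_id = c("K1", "K1", "K1", "K2", NA, NA),
                    category = c("metabolism", "metabolism", "metabolism",
                                 "information", NA, NA),
                    stringsAsFactors = FALSE)
  mj <- majority_function(asg)
  expect_equal(mj$function_id, "K1")
  expect_equal(mj$category, "metabolism")
  expect_false(mj$tie)
  # member order never matters; adding unannotated members never changes it
  mj2 <- majority_function(asg[sample(nrow(asg)), ])
  expect_equal(mj2$function_id, mj$function_id)
  extra <- rbind(asg, data.frame(seq_id = "s7", function_id = NA,
                                 category = NA))
  expect_equal(majority_function(extra)$function_id, "K1")
  # tie: lexicographically smallest, flagged
  tie <- asg[c(1, 2, 4, 4), ]
  mjt <- majority_function(tie)
  expect_equal(mjt$function_id, "K1")
  expect_true(mjt$tie)
  # all unannotated: none
  none <- majority_function(asg[5:6, ])
  expect_true(is.na(none$function_id))
})

test_that("category summaries recover planted origin-function coupling", {
  cfg <- simulation_config(
    n_bacteria = 8, n_archaea = 8, n_eukaryotes = 4, genus_sizes = c(5, 3),
    n_families = c(euk_bact = 90, euk_arch = 60),
    function_probs = c(metabolism_given_bact = 0.7,
                       information_given_arch = 0.8),
    seq_length_range = c(50, 70), seed = 61)
  sim <- simulate_dataset(cfg)
  fams <- sim$truth$families
  # generator-level check: the metabolism|bacterial plant is honoured
  p_met <- mean(fams$function_category[fams$origin == "bacterial"] ==
                "metabolism")
  expect_gt(p_met, 0.6)
  expect_lt(p_met, 0.8)
  # summary-level check on truth-assembled EPCs with truth labels
  es <- epcs_from_truth(sim)
  ann <- data.frame(epc_id = es$epcs$epc_id,
                    function_id = es$epcs$epc_id,
                    category = fams$function_category[
                      match(es$epcs$euk_family, fams$family_id)],
                    tie = FALSE, n_annotated = 1, stringsAsFactors = FALSE)
  es$members <- data.frame(epc_id = es$presence$epc_id,
                           seq_id = paste0(es$presence$epc_id, "_",
                                           es$presence$genome_id),
                           genome_id = es$presence$genome_id,
                           domain = es$presence$domain,
                           stringsAsFactors = FALSE)
  cs <- category_origin_summary(ann, es)
  expect_gt(cs$frac_bacterial_epc[cs$category == "metabolism"], 0.5)
  expect_gt(cs$frac_archaeal_epc[cs$category == "information"], 0.5)
})

test_that("an empty annotation set yields an empty summary, no failure", {
  es <- epcAncestry:::new_epc_set(
    epcs = data.frame(epc_id = "EPC_1", euk_family = "F1",
                      origin = "bacterial", bact_families = "P",
                      arch_families = "", stringsAsFactors = FALSE),
    members = data.frame(epc_id = "EPC_1", seq_id = "e1", genome_id = "E1",
                         domain = "eukaryote", stringsAsFactors = FALSE))
  empty_ann <- data.frame(epc_id = "EPC_1", function_id = NA_character_,
                          category = NA_character_, tie = FALSE,
                          n_annotated = 0L, stringsAsFactors = FALSE)
  cs <- category_origin_summary(empty_ann, es)
  expect_equal(nrow(cs), 0)
})

test_that("presence/absence matrix preserves marginals and block order", {
  genomes <- data.frame(
    genome_id = c("E1", "E2", "E3", "B1", "A1"),
    domain = c("eukaryote", "eukaryote", "eukaryote", "bacteria",
               "archaea"),
    genus = c("e", "e", "e", "g", "a"),
    group = c("Archaeplastida", "Opisthokonta", "Excavata", "Bacteria",
              "Archaea"),
    stringsAsFactors = FALSE)
  es <- make_epcs(
    origins = c("bacterial", "bacterial", "archaeal"),
    prok_members = list("B1", "B1", "a1"),
    euk_members = list(c("E1", "E2", "E3"), "E1", c("E1", "E2", "E3")))
  es$presence$genome_id[es$presence$genome_id == "a1"] <- "A1"
  pam <- presence_absence_matrix(es, genomes)
  expect_equal(sum(pam$matrix), nrow(unique(es$presence)))
  expect_equal(unname(colSums(pam$matrix)[es$epcs$epc_id]),
               unname(as.integer(table(es$presence$epc_id)[
                 es$epcs$epc_id])))
  # the Archaeplastida-confined EPC (EPC_2) sorts before the universal ones
  expect_equal(pam$epc_order[1], "EPC_2")
  # an EPC present in every genome is an all-ones column
  full <- make_epcs("bacterial", list("B1"),
                    list(c("E1", "E2", "E3")))
  full$presence <- rbind(full$presence,
                         data.frame(epc_id = "EPC_1", genome_id = "A1",
                                    domain = "archaea"))
  pam2 <- presence_absence_matrix(full, genomes)
  expect_true(all(pam2$matrix[, "EPC_1"] == 1))
  # unknown genome in an EPC errors
  es_bad <- make_epcs("bacterial", list("B9"), list("E1"))
  expect_error(presence_absence_matrix(es_bad, genomes), "absent from")
})
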