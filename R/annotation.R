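#' A labelled reference set for functional annotation
#'
#' Database-version independent stand-in for a functional reference: labelled
#' protein sequences carrying a function id and a top-level category from the
#' fixed vocabulary (metabolism, information, environmental, cellular,
#' organismal, other).
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param labels `data.frame(seq_id, function_id, category)` covering the
#'   sequences.
#' @return A list of class `"annotation_reference"`.
#' @export
annotation_reference <- function(sequences, labels) {
  sequences <- as_named_character(sequences)
  stopifnot(all(c("seq_id", "function_id", "category") %in% names(labels)))
  vocab <- c("metabolism", "information", "environmental", "cellular",
             "organismal", "other")
  if (!all(labels$category %in% vocab))
    stop("categories must be one of: ", paste(vocab, collapse = ", "))
  if (!all(names(sequences) %in% labels$seq_id))
    stop("every reference sequence needs a label")
  structure(list(sequences = sequences, labels = labels),
            class = "annotation_reference")
}

#' Annotate proteins by best reference hit
#'
#' Each protein receives the function of its single best reference hit
#' passing E <= `evalue_max` and query coverage >= `min_coverage` percent;
#' proteins without such a hit stay unannotated.
#'
#' @param members named character vector or `AAStringSet` of proteins.
#' @param reference an [annotation_reference()].
#' @param evalue_max,min_coverage thresholds (1e-10, 80%).
#' @param scoring a [local_scoring()] scheme.
#' @return `data.frame(seq_id, function_id, category)`; unannotated proteins
#'   get `NA` in both label columns.
#' @export
annotate_proteins <- function(members, reference, evalue_max = 1e-10,
                              min_coverage = 80, scoring = local_scoring()) {
  stopifnot(inherits(reference, "annotation_reference"))
  members <- as_named_character(members)
  hits <- cross_hits(members, reference$sequences, scoring, evalue_max)
  hits <- hits[hits$query %in% names(members) &
               hits$qcov >= min_coverage, , drop = FALSE]
  best <- hits[!duplicated(hits$query), , drop = FALSE]  # hits are sorted
  lab <- reference$labels[match(best$subject, reference$labels$seq_id), ,
                          drop = FALSE]
  out <- data.frame(seq_id = names(members),
                    function_id = NA_character_,
                    category = NA_character_, stringsAsFactors = FALSE)
  m <- match(best$query, out$seq_id)
  out$function_id[m] <- lab$function_id
  out$category[m] <- lab$category
  out
}

#' Majority-rule function for one cluster
#'
#' The modal function over annotated members; unannotated members are
#' ignored; a cluster with no annotated member gets no function. Ties go to
#' the lexicographically smallest function id and are flagged.
#'
#' @param assignments per-protein assignments (rows of
#'   [annotate_proteins()] output) belonging to one EPC.
#' @return A list: `function_id`, `category` (both `NA` if unannotated),
#'   `tie` flag, and the named `votes` vector.
#' @export
majority_function <- function(assignments) {
  ann <- assignments[!is.na(assignments$function_id), , drop = FALSE]
  if (nrow(ann) == 0L)
    return(list(function_id = NA_character_, category = NA_character_,
                tie = FALSE, votes = integer(0)))
  votes <- table(ann$function_id)
  top <- names(votes)[votes == max(votes)]
  win <- min(top)
  list(function_id = win,
       category = ann$category[match(win, ann$function_id)],
       tie = length(top) > 1,
       votes = stats::setNames(as.integer(votes), names(votes)))
}

#' Annotate all EPCs by best hit plus majority rule
#'
#' @param epcs an `"epc_set"` with member-level information.
#' @param seqs named sequences covering the EPC members.
#' @param reference an [annotation_reference()].
#' @inheritParams annotate_proteins
#' @return `data.frame(epc_id, function_id, category, tie, n_annotated)`.
#' @export
epc_annotations <- function(epcs, seqs, reference, evalue_max = 1e-10,
                            min_coverage = 80, scoring = local_scoring()) {
  stopifnot(inherits(epcs, "epc_set"), !is.null(epcs$members))
  seqs <- as_named_character(seqs)
  ids <- unique(epcs$members$seq_id)
  per_protein <- annotate_proteins(seqs[ids], reference, evalue_max,
                                   min_coverage, scoring)
  rows <- lapply(epcs$epcs$epc_id, function(eid) {
    mids <- epcs$members$seq_id[epcs$members$epc_id == eid]
    mj <- majority_function(per_protein[per_protein$seq_id %in% mids, ,
                                        drop = FALSE])
    data.frame(epc_id = eid, function_id = mj$function_id,
               category = mj$category, tie = mj$tie,
               n_annotated = sum(!is.na(per_protein$function_id[
                 per_protein$seq_id %in% mids])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_protein") <- per_protein
  out
}

#' Bacterial/archaeal split per functional category
#'
#' For each top-level category, the proportions of bacterial vs archaeal
#' EPCs among annotated exclusive EPCs, at the cluster level and at the
#' eukaryotic-sequence level (counting the eukaryotic sequences inside
#' those EPCs). Categories with no annotated EPC are omitted with a
#' warning.
#'
#' @param annotations output of [epc_annotations()].
#' @param epcs the matching `"epc_set"` (exclusive origins are used).
#' @return `data.frame(category, n_epcs, frac_bacterial_epc,
#'   frac_archaeal_epc, n_euk_seqs, frac_bacterial_seq, frac_archaeal_seq)`.
#' @export
category_origin_summary <- function(annotations, epcs) {
  stopifnot(inherits(epcs, "epc_set"))
  ann <- annotations[!is.na(annotations$category), , drop = FALSE]
  origin <- stats::setNames(epcs$epcs$origin, epcs$epcs$epc_id)
  ann <- ann[origin[ann$epc_id] %in% c("bacterial", "archaeal"), ,
             drop = FALSE]
  vocab <- c("metabolism", "information", "environmental", "cellular",
             "organismal", "other")
  missing_cats <- setdiff(intersect(vocab, unique(annotations$category)),
                          unique(ann$category))
  if (length(missing_cats) > 0)
    warning("categories with no annotated exclusive EPC omitted: ",
            paste(missing_cats, collapse = ", "))
  if (nrow(ann) == 0L)
    return(data.frame(category = character(0), n_epcs = integer(0),
                      frac_bacterial_epc = numeric(0),
                      frac_archaeal_epc = numeric(0),
                      n_euk_seqs = integer(0),
                      frac_bacterial_seq = numeric(0),
                      frac_archaeal_seq = numeric(0),
                      stringsAsFactors = FALSE))
  mem <- epcs$members
  euk_seq_count <- table(mem$epc_id[mem$domain == "eukaryote"])
  rows <- lapply(sort(unique(ann$category)), function(cc) {
    sub <- ann[ann$category == cc, , drop = FALSE]
    ob <- origin[sub$epc_id] == "bacterial"
    w <- as.integer(euk_seq_count[sub$epc_id])
    w[is.na(w)] <- 0L
    data.frame(category = cc, n_epcs = nrow(sub),
               frac_bacterial_epc = mean(ob),
               frac_archaeal_epc = mean(!ob),
               n_euk_seqs = sum(w),
               frac_bacterial_seq = if (sum(w) > 0) sum(w[ob]) / sum(w)
                 else NA_real_,
               frac_archaeal_seq = if (sum(w) > 0) sum(w[!ob]) / sum(w)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binary presence/absence matrix of EPCs across genomes
#'
#' Rows are genomes (all domains), sorted taxonomically (domain, then group,
#' genus and id); columns are EPCs, sorted by their distribution across
#' eukaryotic groups: group-membership signatures confined to the
#' photosynthetic lineages (Archaeplastida, then with SAR, then with
#' Hacrobia) come first, then the remaining signatures by ascending spread,
#' and ascending presence count within a signature. EPCs that SAR/Hacrobia
#' share with Archaeplastida only are binned with the photosynthetic
#' blocks, reflecting secondary symbioses.
#'
#' @param epcs an `"epc_set"`.
#' @param genomes genome metadata table (`genome_id`, `domain`, `genus`,
#'   `group`).
#' @return A list: `matrix` (0/1, genomes x EPCs), `genome_order`,
#'   `epc_order`.
#' @export
presence_absence_matrix <- function(epcs, genomes) {
  stopifnot(inherits(epcs, "epc_set"))
  pres <- epcs$presence
  unknown <- setdiff(unique(pres$genome_id), genomes$genome_id)
  if (length(unknown) > 0)
    stop("genome in an EPC but absent from metadata: ",
         paste(head(unknown, 3), collapse = ", "))
  dom_rank <- c(eukaryote = 1, bacteria = 2, archaea = 3)
  gord <- genomes$genome_id[order(dom_rank[genomes$domain], genomes$group,
                                  genomes$genus, genomes$genome_id)]
  photo <- c("Archaeplastida", "SAR", "Hacrobia")
  grp <- stats::setNames(genomes$group, genomes$genome_id)
  epc_ids <- epcs$epcs$epc_id
  sig_rank <- vapply(epc_ids, function(eid) {
    eg <- unique(grp[pres$genome_id[pres$epc_id == eid &
                                    pres$domain == "eukaryote"]])
    eg <- sort(eg)
    if (length(eg) == 0) return(99)
    if (all(eg %in% photo)) {
      if (identical(eg, "Archaeplastida")) 1
      else if (all(eg %in% c("Archaeplastida", "SAR")) &&
               "Archaeplastida" %in% eg) 2
      else if ("Archaeplastida" %in% eg) 3
      else 4
    } else 10 + length(eg)
  }, numeric(1))
  pcount <- vapply(epc_ids, function(eid)
    sum(pres$epc_id == eid), numeric(1))
  eord <- epc_ids[order(sig_rank, pcount, epc_ids)]
  M <- matrix(0L, nrow = length(gord), ncol = length(eord),
              dimnames = list(gord, eord))
  if (nrow(pres) > 0)
    M[cbind(match(pres$genome_id, gord), match(pres$epc_id, eord))] <- 1L
  list(matrix = M, genome_order = gord, epc_order = eord)
}
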