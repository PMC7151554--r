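#' Genus-stratified downsampling scheme for bacterial genomes
#'
#' Defines the repeated subsampling used to correct the detection-sensitivity
#' imbalance between the large bacterial and small archaeal genome samples:
#' `n_replicates` random subsets of `sample_size` bacterial genomes (the
#' number of archaea), drawn according to the genus distribution of the
#' whole bacterial set. Per-genus quotas are proportional with
#' largest-remainder integerisation (ties broken towards the larger genus,
#' then by genus name); genomes are drawn uniformly without replacement
#' within each genus. Draws are deterministic given `(seed,
#' replicate_index)`.
#'
#' @param n_replicates number of replicate subsamples (the study design uses
#'   1,000).
#' @param sample_size bacterial genomes per replicate (the study design uses
#'   212, the archaeal genome count).
#' @param genus_table `data.frame(genome_id, genus)` over all bacterial
#'   genomes.
#' @param seed RNG seed for the whole scheme.
#' @return A list of class `"downsample_scheme"`.
#' @export
downsample_scheme <- function(n_replicates = 1000, sample_size = 212,
                              genus_table, seed = 1) {
  stopifnot(is.data.frame(genus_table),
            all(c("genome_id", "genus") %in% names(genus_table)))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (sample_size < 1) stop("sample_size must be >= 1")
  if (sample_size > nrow(genus_table))
    stop("sample_size exceeds the bacterial population")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  structure(list(n_replicates = n_replicates, sample_size = sample_size,
                 genus_table = genus_table[order(genus_table$genome_id), ,
                                           drop = FALSE],
                 seed = seed, rep_seeds = rep_seeds),
            class = "downsample_scheme")
}

#' @rdname downsample_scheme
#' @param scheme a `"downsample_scheme"`.
#' @param replicate_index replicate number in `1..n_replicates`.
#' @return `draw_bacterial_subsample()`: character vector of sampled
#'   bacterial genome ids.
#' @export
draw_bacterial_subsample <- function(scheme, replicate_index) {
  stopifnot(inherits(scheme, "downsample_scheme"))
  if (replicate_index < 1 || replicate_index > scheme$n_replicates)
    stop("replicate_index out of range")
  quotas <- genus_quotas(scheme$genus_table, scheme$sample_size)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scheme$rep_seeds[replicate_index])
  out <- character(0)
  for (g in names(quotas)) {
    ids <- scheme$genus_table$genome_id[scheme$genus_table$genus == g]
    k <- quotas[[g]]
    if (k > 0) out <- c(out, sample(ids, k))
  }
  sort(out)
}

# proportional allocation with largest-remainder rounding
genus_quotas <- function(genus_table, sample_size) {
  sizes <- table(genus_table$genus)
  n <- sum(sizes)
  exact <- sample_size * as.numeric(sizes) / n
  base <- floor(exact)
  frac <- exact - base
  need <- sample_size - sum(base)
  quotas <- stats::setNames(as.integer(base), names(sizes))
  if (need > 0) {
    ord <- order(-frac, -as.numeric(sizes), names(sizes))
    bump <- ord[seq_len(need)]
    quotas[bump] <- quotas[bump] + 1L
  }
  quotas
}

#' Keep only EPCs with an exclusive prokaryotic origin
#'
#' @param epcs an `"epc_set"`.
#' @return The subset with origin `bacterial` or `archaeal` (dual,
#'   ambiguous and recheck-excluded EPCs removed).
#' @export
exclusive_epcs <- function(epcs) {
  stopifnot(inherits(epcs, "epc_set"))
  keep <- epcs$epcs$origin %in% c("bacterial", "archaeal")
  ids <- epcs$epcs$epc_id[keep]
  new_epc_set(epcs$epcs[keep, , drop = FALSE],
              presence = epcs$presence[epcs$presence$epc_id %in% ids, ,
                                       drop = FALSE],
              members = if (!is.null(epcs$members))
                epcs$members[epcs$members$epc_id %in% ids, , drop = FALSE])
}

#' Score one downsampling replicate
#'
#' For each exclusive EPC whose linked prokaryotic family is represented in
#' the replicate (bacterial EPCs: at least one genome of the bacterial
#' subsample in the presence set; archaeal EPCs: at least one genome of
#' `archaeal_set`), every eukaryotic genome in the EPC's presence set gains
#' one count of the matching domain -- once per genome per EPC, regardless
#' of paralog number.
#'
#' @param epcs an `"epc_set"` containing only exclusive EPCs (an EPC with
#'   origin dual/ambiguous raises an error).
#' @param bacterial_sample,archaeal_set character vectors of prokaryotic
#'   genome ids.
#' @param euk_genomes eukaryotic genome ids to report (defaults to those
#'   present in any EPC).
#' @return `data.frame(genome_id, bacterial, archaeal)`.
#' @export
score_replicate <- function(epcs, bacterial_sample, archaeal_set,
                            euk_genomes = NULL) {
  stopifnot(inherits(epcs, "epc_set"))
  bad <- setdiff(unique(epcs$epcs$origin), c("bacterial", "archaeal"))
  if (length(bad) > 0)
    stop("non-exclusive EPC passed to score_replicate (origin: ",
         paste(bad, collapse = ", "), ")")
  pres <- epcs$presence
  if (is.null(euk_genomes))
    euk_genomes <- sort(unique(pres$genome_id[pres$domain == "eukaryote"]))
  origin <- stats::setNames(epcs$epcs$origin, epcs$epcs$epc_id)
  active <- vapply(epcs$epcs$epc_id, function(eid) {
    pg <- pres$genome_id[pres$epc_id == eid & pres$domain != "eukaryote"]
    if (origin[[eid]] == "bacterial") any(pg %in% bacterial_sample)
    else any(pg %in% archaeal_set)
  }, logical(1))
  counts_for <- function(which_origin) {
    ids <- epcs$epcs$epc_id[active & epcs$epcs$origin == which_origin]
    rows <- pres[pres$epc_id %in% ids & pres$domain == "eukaryote", ,
                 drop = FALSE]
    tab <- table(factor(rows$genome_id, levels = euk_genomes))
    as.integer(tab)
  }
  data.frame(genome_id = euk_genomes,
             bacterial = counts_for("bacterial"),
             archaeal = counts_for("archaeal"),
             stringsAsFactors = FALSE)
}

#' Estimate per-genome bacterial/archaeal proportions by downsampling
#'
#' Runs [score_replicate()] over all replicates of a
#' [downsample_scheme()]. Archaeal counts do not depend on the replicate
#' (all archaea are always included), so they are computed once. The
#' default proportion is the ratio of mean counts,
#' `p_bacterial = mean_bact / (mean_bact + mean_arch)` (robust to
#' replicates with zero totals); `mode = "mean_of_ratios"` averages
#' per-replicate ratios instead. Genomes with zero mean total are flagged
#' and get `NA` proportions.
#'
#' @param epcs an `"epc_set"` of exclusive EPCs (see [exclusive_epcs()]).
#' @param scheme a [downsample_scheme()] over the bacterial genomes.
#' @param archaeal_set character vector of all archaeal genome ids.
#' @param euk_genomes eukaryotic genome ids to report.
#' @param mode proportion definition (see above).
#' @return `data.frame(genome_id, mean_bacterial, mean_archaeal,
#'   sd_bacterial, p_bacterial, p_archaeal, zero_total)`.
#' @export
estimate_proportions <- function(epcs, scheme, archaeal_set,
                                 euk_genomes = NULL,
                                 mode = c("ratio_of_means",
                                          "mean_of_ratios")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "downsample_scheme"))
  if (nrow(epcs$epcs) == 0L) stop("no exclusive EPCs to score")
  pres <- epcs$presence
  if (is.null(euk_genomes))
    euk_genomes <- sort(unique(pres$genome_id[pres$domain == "eukaryote"]))
  # archaeal counts: replicate-independent
  arch_ids <- epcs$epcs$epc_id[epcs$epcs$origin == "archaeal"]
  arch_active <- vapply(arch_ids, function(eid)
    any(pres$genome_id[pres$epc_id == eid & pres$domain != "eukaryote"]
        %in% archaeal_set), logical(1))
  arch_rows <- pres[pres$epc_id %in% arch_ids[arch_active] &
                    pres$domain == "eukaryote", , drop = FALSE]
  arch_counts <- as.integer(table(factor(arch_rows$genome_id,
                                         levels = euk_genomes)))
  # bacterial EPC incidence: eukaryote genomes x EPCs, and prok carrier sets
  bact_ids <- epcs$epcs$epc_id[epcs$epcs$origin == "bacterial"]
  carriers <- lapply(bact_ids, function(eid)
    pres$genome_id[pres$epc_id == eid & pres$domain != "eukaryote"])
  inc <- matrix(0L, nrow = length(euk_genomes), ncol = length(bact_ids),
                dimnames = list(euk_genomes, bact_ids))
  bp <- pres[pres$epc_id %in% bact_ids & pres$domain == "eukaryote", ,
             drop = FALSE]
  if (nrow(bp) > 0)
    inc[cbind(match(bp$genome_id, euk_genomes),
              match(bp$epc_id, bact_ids))] <- 1L
  reps <- matrix(0, nrow = length(euk_genomes), ncol = scheme$n_replicates)
  for (r in seq_len(scheme$n_replicates)) {
    samp <- draw_bacterial_subsample(scheme, r)
    act <- vapply(carriers, function(cg) any(cg %in% samp), logical(1))
    reps[, r] <- if (length(act)) inc %*% as.integer(act) else 0
  }
  mean_bact <- rowMeans(reps)
  sd_bact <- apply(reps, 1, stats::sd)
  out <- data.frame(genome_id = euk_genomes,
                    mean_bacterial = mean_bact,
                    mean_archaeal = arch_counts,
                    sd_bacterial = sd_bact,
                    stringsAsFactors = FALSE)
  if (mode == "ratio_of_means") {
    tot <- out$mean_bacterial + out$mean_archaeal
    out$p_bacterial <- ifelse(tot > 0, out$mean_bacterial / tot, NA_real_)
  } else {
    denom <- reps + arch_counts
    pr <- ifelse(denom > 0, reps / denom, NA_real_)
    out$p_bacterial <- rowMeans(pr, na.rm = TRUE)
    out$p_bacterial[is.nan(out$p_bacterial)] <- NA_real_
  }
  out$p_archaeal <- 1 - out$p_bacterial
  out$zero_total <- (out$mean_bacterial + out$mean_archaeal) == 0
  out
}

#' Direct (no-downsampling) ancestry counts
#'
#' The naive estimator: a single pass with the full bacterial and archaeal
#' genome sets. With `sample_size` equal to the whole bacterial population,
#' [estimate_proportions()] reduces exactly to these counts.
#'
#' @inheritParams score_replicate
#' @param bacterial_set all bacterial genome ids.
#' @return As [estimate_proportions()] (with zero spread columns).
#' @export
direct_counts <- function(epcs, bacterial_set, archaeal_set,
                          euk_genomes = NULL) {
  sc <- score_replicate(epcs, bacterial_set, archaeal_set, euk_genomes)
  tot <- sc$bacterial + sc$archaeal
  data.frame(genome_id = sc$genome_id,
             mean_bacterial = as.numeric(sc$bacterial),
             mean_archaeal = as.numeric(sc$archaeal),
             sd_bacterial = 0,
             p_bacterial = ifelse(tot > 0, sc$bacterial / tot, NA_real_),
             p_archaeal = ifelse(tot > 0, sc$archaeal / tot, NA_real_),
             zero_total = tot == 0,
             stringsAsFactors = FALSE)
}

#' Group-level summary of ancestry proportions
#'
#' Unweighted means of the per-genome proportions within each eukaryotic
#' group, plus composite rows (all eukaryotes; with plastids; without
#' plastids; parasites), in the layout of a group proportions table whose
#' archaeal and bacterial columns sum to 1.
#'
#' @param estimates output of [estimate_proportions()].
#' @param genomes genome metadata with `genome_id`, `group`, `plastid`,
#'   `parasite` columns.
#' @param digits optional rounding for the report (the study tables use 2).
#' @return `data.frame(group, n_genomes, p_archaeal, p_bacterial)`.
#' @export
group_summary <- function(estimates, genomes, digits = NULL) {
  meta <- genomes[match(estimates$genome_id, genomes$genome_id), ,
                  drop = FALSE]
  if (anyNA(meta$group)) stop("every genome must be mapped to a group")
  est <- estimates[!is.na(estimates$p_bacterial), , drop = FALSE]
  meta <- meta[!is.na(estimates$p_bacterial), , drop = FALSE]
  row_for <- function(label, sel) {
    if (!any(sel)) return(NULL)
    data.frame(group = label, n_genomes = sum(sel),
               p_archaeal = mean(est$p_archaeal[sel]),
               p_bacterial = mean(est$p_bacterial[sel]),
               stringsAsFactors = FALSE)
  }
  rows <- list(row_for("All eukaryotes", rep(TRUE, nrow(est))),
               row_for("All without plastids", !meta$plastid),
               row_for("All with plastids", meta$plastid))
  for (g in sort(unique(meta$group)))
    rows[[length(rows) + 1L]] <- row_for(g, meta$group == g)
  rows[[length(rows) + 1L]] <- row_for("Parasites", meta$parasite)
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    out$p_archaeal <- round(out$p_archaeal, digits)
    out$p_bacterial <- round(out$p_bacterial, digits)
  }
  rownames(out) <- NULL
  out
}

#' Correlation of ancestry counts with proteome size
#'
#' Squared Pearson correlation between per-genome mean archaeal (bacterial)
#' counts and proteome size.
#'
#' @param estimates output of [estimate_proportions()].
#' @param proteome_sizes named numeric vector: genome_id -> protein count.
#' @return `c(r2_archaeal =, r2_bacterial =)`.
#' @export
size_correlation <- function(estimates, proteome_sizes) {
  if (nrow(estimates) < 3) stop("need at least 3 genomes")
  sizes <- proteome_sizes[estimates$genome_id]
  if (anyNA(sizes)) stop("missing proteome size for some genomes")
  if (stats::sd(sizes) == 0) stop("proteome sizes are constant")
  c(r2_archaeal = unname(cor(estimates$mean_archaeal, sizes)^2),
    r2_bacterial = unname(cor(estimates$mean_bacterial, sizes)^2))
}
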