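#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline; every threshold of
#' the method is a named key defaulting to the study values: E-value cutoff
#' 1e-10; global-identity cutoffs 25% (prokaryotes) and 40% (eukaryotes)
#' for reciprocal best hits; 50% best-hit correspondence and 30% local
#' identity for cluster merging; 80% coverage for annotation; MCL inflation
#' 2; downsampling with as many bacteria per replicate as there are archaea.
#'
#' @param sim an [simulation_config()] (used when `input_dir` is `NULL`).
#' @param input_dir optional dataset directory in [write_dataset()] layout;
#'   when given, the proteomes are read instead of simulated (truth-aware
#'   extras such as the synthetic annotation reference are then skipped
#'   unless `reference` is supplied).
#' @param evalue_max,prok_global_identity,euk_global_identity,
#'   min_correspondence,min_local_identity,annotation_coverage thresholds
#'   (see above).
#' @param inflation,prune_threshold,max_iter,tol MCL controls.
#' @param n_replicates,sample_size downsampling controls; `sample_size =
#'   NULL` uses the archaeal genome count.
#' @param recheck run the other-domain exclusivity recheck.
#' @param annotate run the annotation stage (needs a reference).
#' @param reference optional [annotation_reference()].
#' @param seed master seed: the simulation uses `seed`, the downsampling
#'   scheme `seed + 1`.
#' @return A list of class `"epc_pipeline_config"`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            input_dir = NULL,
                            evalue_max = 1e-10,
                            prok_global_identity = 25,
                            euk_global_identity = 40,
                            min_correspondence = 0.5,
                            min_local_identity = 30,
                            annotation_coverage = 80,
                            inflation = 2,
                            prune_threshold = 1e-5,
                            max_iter = 200,
                            tol = 1e-6,
                            n_replicates = 1000,
                            sample_size = NULL,
                            recheck = TRUE,
                            annotate = TRUE,
                            reference = NULL,
                            seed = 1) {
  structure(as.list(environment()), class = "epc_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override [pipeline_config()]
#' arguments; a `sim:` section overrides [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return An `"epc_pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  y$sim <- NULL
  if (!is.null(simargs$n_families))
    simargs$n_families <- unlist(simargs$n_families)
  if (!is.null(simargs$genus_sizes))
    simargs$genus_sizes <- unlist(simargs$genus_sizes)
  sim <- do.call(simulation_config, if (is.null(simargs)) list() else simargs)
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Run the full ancestry pipeline
#'
#' Orchestrates simulate (or load) -> all-vs-all local search -> reciprocal
#' best hits -> Markov clustering -> family filters -> reciprocal best
#' cluster merging -> origin classification -> exclusivity recheck ->
#' genus-stratified downsampling estimates -> annotation and reporting.
#' The run manifest carries every exclusion counter and the accounting
#' identities are verified (a violation aborts the run). Reruns with the
#' same configuration and seed reproduce identical outputs.
#'
#' @param config an `"epc_pipeline_config"` (or path to a YAML file).
#' @param seed optional override of `config$seed`.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSVs plus a JSON manifest.
#' @return A list of class `"epc_pipeline_result"`: `manifest`, `families`,
#'   `epcs`, `estimates`, `group_summary`, `size_correlation`,
#'   `annotations`, `category_summary`, `presence` (matrix bundle),
#'   `sim`/`genomes`, `scheme`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "epc_pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  config$sim$seed <- config$seed  # master seed drives the simulation too
  sim <- NULL
  if (is.null(config$input_dir)) {
    sim <- simulate_dataset(config$sim)
    sequences <- sim$sequences
    genomes <- sim$genomes
  } else {
    ds <- read_proteome_dir(config$input_dir)
    sequences <- ds$sequences
    genomes <- ds$genomes
  }
  seqs <- as.character(sequences)
  genome_of <- genome_map_from_ids(names(seqs), genomes, sim)
  domain_of_genome <- stats::setNames(genomes$domain, genomes$genome_id)
  domain_of_seq <- unname(domain_of_genome[genome_of[names(seqs)]])
  local <- local_scoring()
  global <- global_scoring()
  # within-domain families
  families <- list(); partitions <- list(); dropped <- list()
  for (dom in c("bacteria", "archaea", "eukaryote")) {
    ids <- names(seqs)[domain_of_seq == dom]
    if (length(ids) == 0) {
      families[[dom]] <- NULL
      next
    }
    h <- all_vs_all_hits(seqs[ids], local, config$evalue_max)
    cutoff <- if (dom == "eukaryote") config$euk_global_identity
      else config$prok_global_identity
    rbh <- reciprocal_best_hits(h, seqs[ids], genome_of, cutoff, global)
    part <- if (nrow(rbh) > 0 || length(ids) > 0)
      mcl_cluster(data.frame(id_a = rbh$id_a, id_b = rbh$id_b,
                             weight = rbh$global_identity,
                             stringsAsFactors = FALSE),
                  nodes = ids, inflation = config$inflation,
                  prune_threshold = config$prune_threshold,
                  max_iter = config$max_iter, tol = config$tol)
    partitions[[dom]] <- part
    fams <- filter_families(part, dom, genome_of)
    dropped[[dom]] <- attr(fams, "dropped")
    families[[dom]] <- fams
  }
  euk_fams <- families[["eukaryote"]]
  prok_fams <- rbind(families[["bacteria"]], families[["archaea"]])
  # interdomain hits: all eukaryote sequences vs all prokaryote sequences
  euk_ids <- names(seqs)[domain_of_seq == "eukaryote"]
  prok_ids <- names(seqs)[domain_of_seq != "eukaryote"]
  inter <- cross_hits(seqs[euk_ids], seqs[prok_ids], local,
                      config$evalue_max)
  in_fam <- c(euk_fams$seq_id, prok_fams$seq_id)
  inter_fam <- inter[inter$query %in% in_fam & inter$subject %in% in_fam, ,
                     drop = FALSE]
  epcs <- assemble_epcs(euk_fams, prok_fams, inter_fam, seqs,
                        config$min_correspondence,
                        config$min_local_identity, config$evalue_max,
                        local = local, global = global,
                        min_prok_global_identity =
                          config$prok_global_identity)
  pre <- table(factor(epcs$epcs$origin,
                      levels = c("bacterial", "archaeal", "dual",
                                 "ambiguous")))
  if (config$recheck) {
    euk_to_prok <- inter[inter$query %in% euk_ids, , drop = FALSE]
    epcs <- recheck_exclusive(epcs, euk_to_prok, seqs,
                              stats::setNames(domain_of_seq, names(seqs)),
                              config$evalue_max,
                              config$prok_global_identity, global)
  }
  n_excl <- sum(epcs$epcs$origin == "excluded_by_recheck")
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_sequences = length(seqs),
    n_genomes = nrow(genomes),
    n_families = lapply(families, function(f)
      if (is.null(f)) 0L else length(unique(f$family_id))),
    n_dropped_seqs = lapply(dropped, length),
    n_euk_specific = attr(epcs, "n_euk_specific"),
    n_bacterial_only = as.integer(pre[["bacterial"]]),
    n_archaeal_only = as.integer(pre[["archaeal"]]),
    n_dual = as.integer(pre[["dual"]]),
    n_ambiguous = as.integer(pre[["ambiguous"]]),
    n_recheck_excluded = n_excl)
  manifest$n_epc <- manifest$n_bacterial_only + manifest$n_archaeal_only +
    manifest$n_dual
  manifest$n_final <- manifest$n_bacterial_only +
    manifest$n_archaeal_only - manifest$n_recheck_excluded
  check_manifest_identities(manifest)
  # downsampling estimates
  bact_meta <- genomes[genomes$domain == "bacteria", , drop = FALSE]
  arch_set <- genomes$genome_id[genomes$domain == "archaea"]
  euk_set <- genomes$genome_id[genomes$domain == "eukaryote"]
  ssize <- if (is.null(config$sample_size)) length(arch_set)
    else config$sample_size
  excl <- exclusive_epcs(epcs)
  estimates <- NULL; scheme <- NULL; groups <- NULL; sizecor <- NULL
  if (nrow(excl$epcs) > 0) {
    scheme <- downsample_scheme(config$n_replicates, ssize,
                                bact_meta[, c("genome_id", "genus")],
                                seed = config$seed + 1L)
    estimates <- estimate_proportions(excl, scheme, arch_set, euk_set)
    groups <- group_summary(estimates, genomes)
    sizes <- table(factor(genome_of[names(seqs)], levels = euk_set))
    sizecor <- tryCatch(
      suppressWarnings(
        size_correlation(estimates, stats::setNames(as.numeric(sizes),
                                                    names(sizes)))),
      error = function(e) NULL)
  } else {
    warning("no exclusive EPCs; estimates skipped")
  }
  # annotation
  annotations <- NULL; catsum <- NULL
  reference <- config$reference
  if (is.null(reference) && !is.null(sim) && isTRUE(config$annotate))
    reference <- annotation_reference_from_simulation(sim)
  if (isTRUE(config$annotate) && !is.null(reference) &&
      nrow(epcs$epcs) > 0) {
    annotations <- epc_annotations(epcs, seqs, reference,
                                   config$evalue_max,
                                   config$annotation_coverage, local)
    catsum <- category_origin_summary(annotations, epcs)
  }
  pam <- presence_absence_matrix(epcs, genomes)
  result <- structure(list(
    manifest = manifest, families = families, partitions = partitions,
    epcs = epcs, estimates = estimates, group_summary = groups,
    size_correlation = sizecor, annotations = annotations,
    category_summary = catsum, presence = pam, sim = sim,
    genomes = genomes, scheme = scheme, config = config),
    class = "epc_pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

genome_map_from_ids <- function(ids, genomes, sim) {
  if (!is.null(sim)) {
    mem <- sim$truth$members
    return(stats::setNames(mem$genome_id, mem$seq_id)[ids])
  }
  # sequence ids are "<genome>_sNNNN"
  g <- sub("_s[0-9]+$", "", ids)
  unknown <- setdiff(unique(g), genomes$genome_id)
  if (length(unknown) > 0)
    stop("cannot map sequences to genomes: ",
         paste(head(unknown, 3), collapse = ", "))
  stats::setNames(g, ids)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (dom in names(result$families))
    if (!is.null(result$families[[dom]]))
      write_tsv(result$families[[dom]],
                file.path(outdir, paste0("families_", dom, ".tsv")))
  write_tsv(result$epcs$epcs, file.path(outdir, "epcs.tsv"))
  write_tsv(result$epcs$presence, file.path(outdir, "epc_presence.tsv"))
  excluded <- result$epcs$epcs[
    result$epcs$epcs$origin %in% c("ambiguous", "excluded_by_recheck"), ,
    drop = FALSE]
  excluded$reason <- ifelse(excluded$origin == "ambiguous",
                            "multiple prokaryote cluster assignment",
                            "other-domain homolog at recheck thresholds")
  write_tsv(excluded, file.path(outdir, "exclusions.tsv"))
  if (!is.null(result$estimates))
    write_tsv(result$estimates, file.path(outdir, "estimates.tsv"))
  if (!is.null(result$group_summary)) {
    gs <- result$group_summary
    gs$p_archaeal <- round(gs$p_archaeal, 2)
    gs$p_bacterial <- round(gs$p_bacterial, 2)
    write_tsv(gs, file.path(outdir, "group_summary.tsv"))
  }
  if (!is.null(result$category_summary))
    write_tsv(result$category_summary,
              file.path(outdir, "category_summary.tsv"))
  pm <- result$presence$matrix
  write_tsv(data.frame(genome_id = rownames(pm), pm, check.names = FALSE),
            file.path(outdir, "presence_matrix.tsv"))
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.epc_pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("EPC pipeline run (seed ", m$seed, ")\n", sep = "")
  cat("  sequences: ", m$n_sequences, " in ", m$n_genomes, " genomes\n",
      sep = "")
  cat("  EPCs: ", m$n_epc, " = ", m$n_bacterial_only, " bacterial + ",
      m$n_archaeal_only, " archaeal + ", m$n_dual, " dual; ",
      m$n_ambiguous, " ambiguous excluded\n", sep = "")
  cat("  after recheck: ", m$n_final, " (", m$n_recheck_excluded,
      " excluded)\n", sep = "")
  if (!is.null(x$estimates)) {
    p <- mean(x$estimates$p_bacterial, na.rm = TRUE)
    cat(sprintf("  mean p_bacterial across eukaryote genomes: %.3f\n", p))
  }
  invisible(x)
}
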