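#' Configuration for the synthetic proteome generator
#'
#' Builds the configuration for [simulate_dataset()]. The generator plants a
#' fully known homology/origin structure: gene families of five categories
#' (eukaryote-specific, eukaryote+bacteria, eukaryote+archaea,
#' eukaryote+both-domains, prokaryote-only) evolved from random ancestral
#' proteins by substitution-only mutation, a skewed bacterial genus-size
#' distribution, patchy per-genome family presence with elevated loss of
#' bacteria-linked families in parasite-flagged genomes, and family-level
#' function labels correlated with origin (metabolism with bacterial,
#' information with archaeal families).
#'
#' Pairwise identity targets are realised through a star phylogeny: family
#' members diverge from a family (or domain) ancestor with per-branch
#' retention chosen so that realised pairwise identities land on the
#' within-domain and interdomain targets (within +/- a few points).
#'
#' @param n_bacteria,n_archaea,n_eukaryotes genome counts per domain.
#' @param genus_sizes per-genus bacterial genome counts; must sum to
#'   `n_bacteria` (archaea and eukaryotes are not genus-structured: only
#'   bacteria are downsampled).
#' @param n_families named counts for the five planted categories
#'   (`euk_specific`, `euk_bact`, `euk_arch`, `euk_dual`, `prok_only`).
#' @param within_domain_identity target pairwise percent identity between
#'   family members of the same domain.
#' @param interdomain_identity target percent identity between eukaryotic
#'   and prokaryotic members of shared families.
#' @param presence_prob probability that a genome of a participating domain
#'   carries a given family. A scalar applies to all domains; a named
#'   per-domain vector (`bacteria`, `archaea`, `eukaryote`) sets one
#'   probability per domain; a per-domain *range* (length-2 element in a
#'   named list) draws an independent per-family prevalence uniformly from
#'   that range, modelling patchy presence with common and rare families.
#' @param parasite_ids eukaryote genome ids (e.g. `"E002"`) flagged as
#'   parasites.
#' @param parasite_loss_multiplier factor by which the presence probability
#'   of bacteria-linked (`euk_bact`) families is divided in parasite genomes.
#' @param function_probs `c(metabolism_given_bact=, information_given_arch=)`:
#'   probability that a `euk_bact` family is labelled metabolism and a
#'   `euk_arch` family information; other labels drawn uniformly.
#' @param seq_length_range amino-acid length range for family ancestors.
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return A list of class `"epc_sim_config"`, with the derived
#'   `planted_bacterial_fraction` = euk_bact / (euk_bact + euk_arch).
#' @export
simulation_config <- function(n_bacteria = 30,
                              n_archaea = 12,
                              n_eukaryotes = 8,
                              genus_sizes = c(12, 8, 5, 3, 2),
                              n_families = c(euk_specific = 10, euk_bact = 60,
                                             euk_arch = 40, euk_dual = 5,
                                             prok_only = 5),
                              within_domain_identity = 80,
                              interdomain_identity = 45,
                              presence_prob = 0.7,
                              parasite_ids = character(0),
                              parasite_loss_multiplier = 3,
                              function_probs = c(metabolism_given_bact = 0.7,
                                                 information_given_arch = 0.8),
                              seq_length_range = c(120, 200),
                              seed = 1) {
  cats <- c("euk_specific", "euk_bact", "euk_arch", "euk_dual", "prok_only")
  fam <- stats::setNames(rep(0L, 5), cats)
  fam[names(n_families)] <- as.integer(n_families)
  if (any(fam < 0) || n_bacteria < 0 || n_archaea < 0 || n_eukaryotes < 0)
    stop("counts must be nonnegative")
  if (sum(genus_sizes) != n_bacteria)
    stop("genus_sizes must sum to n_bacteria")
  pp <- normalize_presence(presence_prob)
  if (any(function_probs < 0 | function_probs > 1))
    stop("function_probs must be in [0, 1]")
  if (!(within_domain_identity > interdomain_identity))
    stop("within_domain_identity must exceed interdomain_identity")
  if (interdomain_identity <= 25)
    warning("interdomain identity at or below the 25% global-identity ",
            "cutoff; planted homologs may not be recoverable")
  n_euk_fams <- sum(fam[c("euk_specific", "euk_bact", "euk_arch", "euk_dual")])
  if (n_eukaryotes == 0 && n_euk_fams > 0)
    stop("zero eukaryote genomes but nonzero eukaryote family counts")
  structure(list(
    n_bacteria = n_bacteria, n_archaea = n_archaea,
    n_eukaryotes = n_eukaryotes, genus_sizes = genus_sizes,
    n_families = fam,
    planted_bacterial_fraction =
      if (fam["euk_bact"] + fam["euk_arch"] > 0)
        unname(fam["euk_bact"] / (fam["euk_bact"] + fam["euk_arch"]))
      else NA_real_,
    within_domain_identity = within_domain_identity,
    interdomain_identity = interdomain_identity,
    presence_prob = pp,
    parasite_ids = parasite_ids,
    parasite_loss_multiplier = parasite_loss_multiplier,
    function_probs = function_probs,
    seq_length_range = seq_length_range,
    seed = seed), class = "epc_sim_config")
}

#' Substitution-only sequence evolution
#'
#' Returns a length-preserving descendant of `ancestor` in which each
#' position is substituted independently with probability
#' `1 - target_identity/100`; substitutions are uniform over the 19
#' alternative amino acids. `target_identity = 100` returns the ancestor
#' unchanged; `target_identity = 0` substitutes every position (the
#' descendant shares no position with the ancestor).
#'
#' @param ancestor protein sequence (character scalar or `AAString`).
#' @param target_identity expected percent of unchanged positions, in
#'   `[0, 100]`.
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored on exit).
#' @return Character scalar.
#' @export
mutate_sequence <- function(ancestor, target_identity, seed = NULL) {
  ancestor <- as.character(ancestor)
  if (length(ancestor) != 1L || is.na(ancestor) || nchar(ancestor) == 0L)
    stop("ancestor must be a single nonempty sequence")
  if (target_identity < 0 || target_identity > 100)
    stop("target_identity must be in [0, 100]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  alph <- aa_alphabet()
  chars <- strsplit(ancestor, "")[[1]]
  idx <- match(chars, alph)
  if (anyNA(idx)) stop("ancestor contains non-standard residues")
  hit <- runif(length(idx)) < (1 - target_identity / 100)
  if (any(hit)) {
    shift <- sample.int(19L, sum(hit), replace = TRUE)
    idx[hit] <- (idx[hit] - 1L + shift) %% 20L + 1L
  }
  paste(alph[idx], collapse = "")
}

#' Simulate a multi-domain proteome dataset with planted structure
#'
#' Generates one protein set per genome plus a truth table recording the
#' planted family of every sequence, the family category, origin label
#' (`bacterial`, `archaeal`, `dual`, `none`) and function category. Family
#' presence per genome is drawn independently with the per-domain presence
#' probability; in parasite-flagged eukaryote genomes the presence
#' probability of `euk_bact` families is divided by
#' `parasite_loss_multiplier`.
#'
#' @param config an [simulation_config()] object.
#' @return A list of class `"epc_simulation"`: `sequences` (named
#'   `AAStringSet`), `genomes` (metadata `data.frame`: genome_id, domain,
#'   genus, group, plastid, parasite), `truth` (list of `families` and
#'   `members` data frames), `ancestors` (family root sequences, named) and
#'   the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "epc_sim_config"))
  set.seed(config$seed)
  alph <- aa_alphabet()
  genomes <- simulate_genome_table(config)
  fam <- config$n_families
  cats <- rep(names(fam), fam)
  n_fam <- length(cats)
  fam_ids <- sprintf("fam%04d", seq_len(n_fam))
  p_member <- sqrt(config$within_domain_identity / 100)
  c_half <- sqrt(config$interdomain_identity / config$within_domain_identity)
  func_cats <- c("metabolism", "information", "environmental", "cellular",
                 "organismal", "other")
  origin_of <- c(euk_specific = "none", euk_bact = "bacterial",
                 euk_arch = "archaeal", euk_dual = "dual", prok_only = "none")
  pp <- config$presence_prob
  by_dom <- split(genomes$genome_id, genomes$domain)
  seq_ids <- character(0); seq_strs <- character(0)
  mem_seq <- character(0); mem_gen <- character(0); mem_fam <- character(0)
  per_genome_n <- stats::setNames(integer(nrow(genomes)), genomes$genome_id)
  roots <- character(n_fam)
  func_lab <- character(n_fam)
  for (f in seq_len(n_fam)) {
    cat_f <- cats[f]
    L <- sample(seq(config$seq_length_range[1], config$seq_length_range[2]), 1)
    root <- paste(sample(alph, L, replace = TRUE), collapse = "")
    roots[f] <- root
    func_lab[f] <- draw_function_label(cat_f, config$function_probs, func_cats)
    domains <- switch(cat_f,
                      euk_specific = "eukaryote",
                      euk_bact = c("eukaryote", "bacteria"),
                      euk_arch = c("eukaryote", "archaea"),
                      euk_dual = c("eukaryote", "bacteria", "archaea"),
                      prok_only = c("bacteria", "archaea"))
    interdomain <- length(domains) > 1 && "eukaryote" %in% domains
    euk_anc <- root; prok_anc <- root
    if (interdomain) {
      euk_anc <- mutate_sequence(root, 100 * c_half)
      prok_anc <- mutate_sequence(root, 100 * c_half)
    }
    for (dom in domains) {
      anc <- if (dom == "eukaryote") euk_anc else prok_anc
      rng <- pp[[dom]]
      prevalence <- if (rng[1] < rng[2]) runif(1, rng[1], rng[2]) else rng[1]
      for (g in by_dom[[dom]]) {
        prob <- prevalence
        if (dom == "eukaryote" && cat_f == "euk_bact" &&
            g %in% config$parasite_ids)
          prob <- prob / config$parasite_loss_multiplier
        if (runif(1) >= prob) next
        per_genome_n[g] <- per_genome_n[g] + 1L
        sid <- sprintf("%s_s%04d", g, per_genome_n[g])
        seq_ids <- c(seq_ids, sid)
        seq_strs <- c(seq_strs, mutate_sequence(anc, 100 * p_member))
        mem_seq <- c(mem_seq, sid); mem_gen <- c(mem_gen, g)
        mem_fam <- c(mem_fam, fam_ids[f])
      }
    }
  }
  sequences <- Biostrings::AAStringSet(stats::setNames(seq_strs, seq_ids))
  families <- data.frame(family_id = fam_ids, category = cats,
                         origin = unname(origin_of[cats]),
                         function_category = func_lab,
                         stringsAsFactors = FALSE)
  members <- data.frame(seq_id = mem_seq, genome_id = mem_gen,
                        family_id = mem_fam, stringsAsFactors = FALSE)
  structure(list(sequences = sequences, genomes = genomes,
                 truth = list(families = families, members = members),
                 ancestors = stats::setNames(roots, fam_ids),
                 config = config),
            class = "epc_simulation")
}

# normalize presence_prob to a named list of c(lo, hi) prevalence ranges
normalize_presence <- function(presence_prob) {
  doms <- c("bacteria", "archaea", "eukaryote")
  pp <- presence_prob
  if (!is.list(pp)) {
    if (length(pp) == 1L && is.null(names(pp)))
      pp <- stats::setNames(as.list(rep(pp, 3)), doms)
    else if (!is.null(names(pp)))
      pp <- as.list(pp)
    else stop("presence_prob must be a scalar, named vector or named list")
  }
  if (!all(doms %in% names(pp)))
    stop("presence_prob must cover domains: ", paste(doms, collapse = ", "))
  out <- lapply(pp[doms], function(x) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(x < 0 | x > 1) || x[1] > x[2])
      stop("presence_prob entries must be one probability or an ",
           "increasing range within [0, 1]")
    as.numeric(x)
  })
  out
}

draw_function_label <- function(category, probs, func_cats) {
  if (category == "euk_bact") {
    if (runif(1) < probs[["metabolism_given_bact"]]) return("metabolism")
    return(sample(setdiff(func_cats, "metabolism"), 1))
  }
  if (category == "euk_arch") {
    if (runif(1) < probs[["information_given_arch"]]) return("information")
    return(sample(setdiff(func_cats, "information"), 1))
  }
  sample(func_cats, 1)
}

simulate_genome_table <- function(config) {
  euk_groups <- c("Archaeplastida", "Opisthokonta", "SAR", "Excavata",
                  "Hacrobia", "Mycetozoa")
  photosynthetic <- c("Archaeplastida", "SAR", "Hacrobia")
  bact_ids <- sprintf("B%03d", seq_len(config$n_bacteria))
  arch_ids <- sprintf("A%03d", seq_len(config$n_archaea))
  euk_ids <- sprintf("E%03d", seq_len(config$n_eukaryotes))
  genus <- rep(sprintf("genus_%02d", seq_along(config$genus_sizes)),
               config$genus_sizes)
  grp <- rep_len(euk_groups, max(config$n_eukaryotes, 1))
  bad <- setdiff(config$parasite_ids, euk_ids)
  if (length(bad) > 0)
    stop("parasite_ids not among eukaryote genomes: ",
         paste(bad, collapse = ", "))
  rbind(
    data.frame(genome_id = bact_ids, domain = "bacteria", genus = genus,
               group = "Bacteria", plastid = FALSE, parasite = FALSE,
               stringsAsFactors = FALSE),
    data.frame(genome_id = arch_ids, domain = "archaea", genus = "archaea",
               group = "Archaea", plastid = FALSE, parasite = FALSE,
               stringsAsFactors = FALSE),
    if (config$n_eukaryotes > 0)
      data.frame(genome_id = euk_ids, domain = "eukaryote",
                 genus = "eukaryote", group = grp[seq_along(euk_ids)],
                 plastid = grp[seq_along(euk_ids)] %in% photosynthetic,
                 parasite = euk_ids %in% config$parasite_ids,
                 stringsAsFactors = FALSE))
}

#' Assemble ground-truth EPCs from a simulation
#'
#' Bypasses the homology-detection stages and builds the eukaryote-prokaryote
#' cluster set directly from a simulation's truth table, applying the same
#' family-size/species filters as the pipeline. Used to study the
#' downsampling estimator in isolation from alignment and clustering (the
#' estimator sees exactly the planted families, so any bias observed is the
#' estimator's own).
#'
#' @param sim an `"epc_simulation"` object.
#' @param min_prok_seqs,min_euk_species filters as in [filter_families()].
#' @return An `"epc_set"` (see [assemble_epcs()]).
#' @export
epcs_from_truth <- function(sim, min_prok_seqs = 5, min_euk_species = 2) {
  stopifnot(inherits(sim, "epc_simulation"))
  mem <- sim$truth$members
  mem$domain <- sim$genomes$domain[match(mem$genome_id, sim$genomes$genome_id)]
  fams <- sim$truth$families
  epc_rows <- list(); pres_rows <- list()
  for (k in seq_len(nrow(fams))) {
    if (!fams$category[k] %in% c("euk_bact", "euk_arch", "euk_dual")) next
    fm <- mem[mem$family_id == fams$family_id[k], , drop = FALSE]
    euk_g <- unique(fm$genome_id[fm$domain == "eukaryote"])
    bact_n <- sum(fm$domain == "bacteria")
    arch_n <- sum(fm$domain == "archaea")
    if (length(euk_g) < min_euk_species) next
    has_bact <- bact_n >= min_prok_seqs
    has_arch <- arch_n >= min_prok_seqs
    origin <- if (has_bact && has_arch) "dual"
      else if (has_bact) "bacterial"
      else if (has_arch) "archaeal"
      else next
    fid <- fams$family_id[k]
    keep_dom <- c("eukaryote", if (has_bact) "bacteria",
                  if (has_arch) "archaea")
    pres_g <- unique(fm[fm$domain %in% keep_dom,
                        c("genome_id", "domain")])
    epc_rows[[length(epc_rows) + 1L]] <- data.frame(
      epc_id = fid, euk_family = fid,
      origin = origin,
      bact_families = if (has_bact) paste0(fid, "_b") else "",
      arch_families = if (has_arch) paste0(fid, "_a") else "",
      stringsAsFactors = FALSE)
    pres_rows[[length(pres_rows) + 1L]] <- data.frame(
      epc_id = fid, genome_id = pres_g$genome_id, domain = pres_g$domain,
      stringsAsFactors = FALSE)
  }
  new_epc_set(do.call(rbind, epc_rows), do.call(rbind, pres_rows))
}

#' Build a synthetic annotation reference from a simulation
#'
#' Labelled reference proteins for the annotation stage: one entry per
#' planted family (its ancestral sequence), labelled with a per-family
#' function id and the family's function category. Members of a family find
#' their own ancestor as best hit, so majority voting recovers the planted
#' function label.
#'
#' @param sim an `"epc_simulation"` object.
#' @return An [annotation_reference()] object.
#' @export
annotation_reference_from_simulation <- function(sim) {
  stopifnot(inherits(sim, "epc_simulation"))
  fams <- sim$truth$families
  ids <- paste0("ref_", fams$family_id)
  annotation_reference(
    sequences = stats::setNames(unname(sim$ancestors), ids),
    labels = data.frame(seq_id = ids,
                        function_id = sprintf("K%05d", seq_len(nrow(fams))),
                        category = fams$function_category,
                        stringsAsFactors = FALSE))
}
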