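#' Link eukaryotic and prokaryotic families by reciprocal best cluster
#'
#' Cluster-level analogue of reciprocal best hits: a eukaryotic family is
#' linked to a prokaryotic family when at least `min_correspondence` of each
#' family's best interdomain hits land in the other family. Only qualifying
#' hits count: E-value at most `evalue_max` and local percent identity at
#' least `min_local_identity` (the 50% correspondence / 30% identity rule).
#' Best hits are taken per prokaryotic domain, since bacteria and archaea
#' are clustered separately; members without a qualifying hit are excluded
#' from the correspondence denominator (`denominator = "hit_bearing"`) or
#' kept in it (`"all"`).
#'
#' @param euk_families,prok_families family tables from [filter_families()]
#'   (`prok_families` may combine the bacterial and archaeal tables).
#' @param interdomain_hits directed hit table from [cross_hits()] between
#'   the eukaryotic and prokaryotic sequences of the retained families.
#' @param min_correspondence correspondence threshold (default 0.5).
#' @param min_local_identity local identity threshold in percent (30).
#' @param evalue_max E-value cutoff (1e-10).
#' @param denominator see above.
#' @return `data.frame(euk_family, prok_family, prok_domain, forward,
#'   reverse)` with both correspondences at or above the threshold.
#' @export
link_clusters <- function(euk_families, prok_families, interdomain_hits,
                          min_correspondence = 0.5, min_local_identity = 30,
                          evalue_max = 1e-10,
                          denominator = c("hit_bearing", "all")) {
  denominator <- match.arg(denominator)
  fam_of_euk <- stats::setNames(euk_families$family_id, euk_families$seq_id)
  fam_of_prok <- stats::setNames(prok_families$family_id,
                                 prok_families$seq_id)
  dom_of_prok_fam <- stats::setNames(prok_families$domain,
                                     prok_families$family_id)
  q <- interdomain_hits
  q <- q[q$evalue <= evalue_max & q$pident_local >= min_local_identity, ,
         drop = FALSE]
  in_euk_q <- q$query %in% names(fam_of_euk)
  in_prok_q <- q$query %in% names(fam_of_prok)
  stray <- unique(c(q$query[!(in_euk_q | in_prok_q)],
                    q$subject[!(q$subject %in% names(fam_of_euk) |
                                q$subject %in% names(fam_of_prok))]))
  if (length(stray) > 0)
    stop("hit references sequence outside any family: ",
         paste(head(stray, 3), collapse = ", "))
  empty <- data.frame(euk_family = character(0), prok_family = character(0),
                      prok_domain = character(0), forward = numeric(0),
                      reverse = numeric(0), stringsAsFactors = FALSE)
  fwd <- q[in_euk_q & q$subject %in% names(fam_of_prok), , drop = FALSE]
  rev <- q[in_prok_q & q$subject %in% names(fam_of_euk), , drop = FALSE]
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  # best hit of each eukaryotic member per prokaryotic domain
  fwd$sdom <- unname(dom_of_prok_fam[fam_of_prok[fwd$subject]])
  ordf <- order(fwd$query, fwd$sdom, fwd$evalue, -fwd$bitscore, fwd$subject)
  fwd <- fwd[ordf, , drop = FALSE]
  bestf <- fwd[!duplicated(paste(fwd$query, fwd$sdom, sep = "\r")), ,
               drop = FALSE]
  # best eukaryotic hit of each prokaryotic member
  ordr <- order(rev$query, rev$evalue, -rev$bitscore, rev$subject)
  rev <- rev[ordr, , drop = FALSE]
  bestr <- rev[!duplicated(rev$query), , drop = FALSE]
  euk_size <- table(euk_families$family_id)
  prok_size <- table(prok_families$family_id)
  # forward correspondence
  ftab <- table(fam = fam_of_euk[bestf$query],
                pfam = fam_of_prok[bestf$subject])
  fdenom_hit <- table(fam = fam_of_euk[bestf$query], dom = bestf$sdom)
  # reverse correspondence
  rtab <- table(pfam = fam_of_prok[bestr$query],
                efam = fam_of_euk[bestr$subject])
  rdenom_hit <- table(fam_of_prok[bestr$query])
  out <- list()
  for (ef in rownames(ftab)) {
    for (pf in colnames(ftab)) {
      n_to <- ftab[ef, pf]
      if (n_to == 0) next
      pd <- unname(dom_of_prok_fam[pf])
      fden <- if (denominator == "all") euk_size[ef]
        else fdenom_hit[ef, pd]
      fcor <- as.numeric(n_to) / as.numeric(fden)
      n_back <- if (pf %in% rownames(rtab) && ef %in% colnames(rtab))
        rtab[pf, ef] else 0
      rden <- if (denominator == "all") prok_size[pf]
        else if (pf %in% names(rdenom_hit)) rdenom_hit[[pf]] else 0
      rcor <- if (rden > 0) as.numeric(n_back) / as.numeric(rden) else 0
      if (fcor >= min_correspondence && rcor >= min_correspondence)
        out[[length(out) + 1L]] <- data.frame(
          euk_family = ef, prok_family = pf, prok_domain = pd,
          forward = fcor, reverse = rcor, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$euk_family, res$prok_family), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify the origin of one eukaryotic family from its cluster links
#'
#' Decision rule: a single bacterial link gives origin `bacterial`; a single
#' archaeal link `archaeal`; one bacterial plus one archaeal link whose
#' prokaryotic families are themselves homologous gives `dual` (a merged
#' EPC, excluded from the proportion estimates); links to multiple
#' non-homologous prokaryotic families give `ambiguous` (excluded entirely);
#' no links means the family is eukaryote-specific and not an EPC.
#'
#' @param euk_family a eukaryotic family id.
#' @param links rows of [link_clusters()] output for that family.
#' @param prok_homologous `function(fam1, fam2)` returning TRUE if two
#'   prokaryotic families are homologous (at least one cross pair passing
#'   E <= 1e-10 and global identity >= 25%).
#' @return `NULL` for a eukaryote-specific family, else a list with
#'   `origin`, `bact_families`, `arch_families`.
#' @export
classify_epc <- function(euk_family, links, prok_homologous) {
  stopifnot(all(links$euk_family == euk_family))
  if (nrow(links) == 0L) return(NULL)
  bf <- links$prok_family[links$prok_domain == "bacteria"]
  af <- links$prok_family[links$prok_domain == "archaea"]
  origin <-
    if (length(bf) == 1L && length(af) == 0L) "bacterial"
    else if (length(af) == 1L && length(bf) == 0L) "archaeal"
    else if (length(bf) == 1L && length(af) == 1L) {
      if (isTRUE(prok_homologous(bf, af))) "dual" else "ambiguous"
    } else "ambiguous"
  list(origin = origin, bact_families = bf, arch_families = af)
}

#' Assemble eukaryote-prokaryote clusters (EPCs)
#'
#' Runs [link_clusters()] and [classify_epc()] over all retained eukaryotic
#' families and builds the EPC set: per EPC the origin label, the linked
#' prokaryotic families, the member sequences and the genome presence set
#' (each genome recorded once per EPC, so gene duplications do not inflate
#' the counts).
#'
#' @inheritParams link_clusters
#' @param seqs the named sequences underlying the hit table (for the
#'   prokaryote-prokaryote homology check behind dual classification).
#' @param local,global scoring schemes for that check.
#' @param min_prok_global_identity global-identity threshold of the
#'   homology check (25%).
#' @return An object of class `"epc_set"`: `epcs` (epc_id, euk_family,
#'   origin, bact_families, arch_families), `presence` (epc_id, genome_id,
#'   domain; unique), `members` (epc_id, seq_id, genome_id, domain).
#'   Attribute `"n_euk_specific"` counts eukaryotic families with no link.
#' @export
assemble_epcs <- function(euk_families, prok_families, interdomain_hits,
                          seqs, min_correspondence = 0.5,
                          min_local_identity = 30, evalue_max = 1e-10,
                          denominator = c("hit_bearing", "all"),
                          local = local_scoring(), global = global_scoring(),
                          min_prok_global_identity = 25) {
  denominator <- match.arg(denominator)
  links <- link_clusters(euk_families, prok_families, interdomain_hits,
                         min_correspondence, min_local_identity, evalue_max,
                         denominator)
  homolog <- prok_homology_checker(seqs, prok_families, local, global,
                                   evalue_max, min_prok_global_identity)
  all_fams <- sort(unique(euk_families$family_id))
  gmap <- family_genome_map(rbind(euk_families, prok_families))
  epc_rows <- list(); mem_rows <- list()
  n_specific <- 0L
  for (ef in all_fams) {
    cl <- classify_epc(ef, links[links$euk_family == ef, , drop = FALSE],
                       homolog)
    if (is.null(cl)) { n_specific <- n_specific + 1L; next }
    fams_in <- c(ef,
                 if (cl$origin != "ambiguous") c(cl$bact_families,
                                                 cl$arch_families))
    mem <- gmap[gmap$family_id %in% fams_in, , drop = FALSE]
    epc_id <- paste0("EPC_", ef)
    epc_rows[[length(epc_rows) + 1L]] <- data.frame(
      epc_id = epc_id, euk_family = ef, origin = cl$origin,
      bact_families = paste(cl$bact_families, collapse = ","),
      arch_families = paste(cl$arch_families, collapse = ","),
      stringsAsFactors = FALSE)
    mem_rows[[length(mem_rows) + 1L]] <- data.frame(
      epc_id = epc_id, seq_id = mem$seq_id, genome_id = mem$genome_id,
      domain = mem$domain, stringsAsFactors = FALSE)
  }
  epcs <- if (length(epc_rows)) do.call(rbind, epc_rows) else
    data.frame(epc_id = character(0), euk_family = character(0),
               origin = character(0), bact_families = character(0),
               arch_families = character(0), stringsAsFactors = FALSE)
  members <- if (length(mem_rows)) do.call(rbind, mem_rows) else NULL
  out <- new_epc_set(epcs, presence = NULL, members = members)
  attr(out, "n_euk_specific") <- n_specific
  out
}

family_genome_map <- function(families) {
  families[, c("family_id", "seq_id", "genome_id", "domain")]
}

# memoised pairwise-family homology check
prok_homology_checker <- function(seqs, prok_families, local, global,
                                  evalue_max, min_global_identity) {
  seqs <- as_named_character(seqs)
  cache <- new.env(parent = emptyenv())
  function(f1, f2) {
    key <- paste(sort(c(f1, f2)), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m1 <- prok_families$seq_id[prok_families$family_id == f1]
    m2 <- prok_families$seq_id[prok_families$family_id == f2]
    ans <- FALSE
    if (length(m1) > 0 && length(m2) > 0) {
      h <- cross_hits(seqs[m1], seqs[m2], local, evalue_max)
      h <- h[h$query %in% m1, , drop = FALSE]
      if (nrow(h) > 0) {
        gi <- vapply(seq_len(nrow(h)), function(k)
          global_identity(seqs[[h$query[k]]], seqs[[h$subject[k]]], global),
          numeric(1))
        ans <- any(gi >= min_global_identity)
      }
    }
    cache[[key]] <- ans
    ans
  }
}

new_epc_set <- function(epcs, presence = NULL, members = NULL) {
  if (is.null(epcs) || nrow(epcs) == 0L)
    epcs <- data.frame(epc_id = character(0), euk_family = character(0),
                       origin = character(0), bact_families = character(0),
                       arch_families = character(0), stringsAsFactors = FALSE)
  if (is.null(presence)) {
    if (!is.null(members) && nrow(members) > 0) {
      presence <- unique(members[, c("epc_id", "genome_id", "domain")])
      rownames(presence) <- NULL
    } else {
      presence <- data.frame(epc_id = character(0), genome_id = character(0),
                             domain = character(0), stringsAsFactors = FALSE)
    }
  }
  structure(list(epcs = epcs, presence = presence, members = members),
            class = "epc_set")
}

#' @export
print.epc_set <- function(x, ...) {
  cat("epc_set:", nrow(x$epcs), "EPCs (",
      paste(sprintf("%s=%d", names(table(x$epcs$origin)),
                    as.integer(table(x$epcs$origin))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Recheck exclusive EPCs against the other prokaryotic domain
#'
#' EPCs assigned a single bacterial (archaeal) cluster exclusively are
#' rechecked for homologs in the remaining prokaryotic domain: if any
#' eukaryotic member of the EPC has a hit there passing E <= `evalue_max`
#' and global identity >= `min_global_identity` (25%), the EPC's origin is
#' set to `excluded_by_recheck`. The operation is idempotent: already
#' excluded or non-exclusive EPCs are left untouched.
#'
#' @param epcs an `"epc_set"` from [assemble_epcs()].
#' @param hits directed eukaryote-vs-prokaryote hit table covering all
#'   prokaryotic sequences of the dataset (clustered or not).
#' @param seqs named sequences (for the lazy global-identity check).
#' @param domain_map named vector: sequence id -> domain, covering all
#'   prokaryotic sequences in `hits`.
#' @param evalue_max,min_global_identity thresholds (1e-10, 25%).
#' @param global a [global_scoring()] scheme.
#' @return The `"epc_set"` with updated origins.
#' @export
recheck_exclusive <- function(epcs, hits, seqs, domain_map,
                              evalue_max = 1e-10, min_global_identity = 25,
                              global = global_scoring()) {
  stopifnot(inherits(epcs, "epc_set"))
  if (is.null(epcs$members))
    stop("recheck requires member-level EPC information")
  seqs <- as_named_character(seqs)
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  h$sdom <- unname(domain_map[h$subject])
  for (k in seq_len(nrow(epcs$epcs))) {
    origin <- epcs$epcs$origin[k]
    if (!origin %in% c("bacterial", "archaeal")) next
    other <- if (origin == "bacterial") "archaea" else "bacteria"
    mem <- epcs$members
    euk_ids <- mem$seq_id[mem$epc_id == epcs$epcs$epc_id[k] &
                          mem$domain == "eukaryote"]
    cand <- h[h$query %in% euk_ids & h$sdom == other, , drop = FALSE]
    if (nrow(cand) == 0L) next
    for (r in seq_len(nrow(cand))) {
      gi <- global_identity(seqs[[cand$query[r]]], seqs[[cand$subject[r]]],
                            global)
      if (gi >= min_global_identity) {
        epcs$epcs$origin[k] <- "excluded_by_recheck"
        break
      }
    }
  }
  epcs
}
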