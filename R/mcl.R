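#' Markov clustering of a weighted similarity graph
#'
#' Clusters the reciprocal-best-hit similarity graph of one domain by Markov
#' clustering (MCL): the column-stochastic random-walk matrix of the graph
#' (with self-loops) is iteratively expanded (matrix squaring) and inflated
#' (entrywise power then column renormalisation), pruning entries below
#' `prune_threshold`, until the matrix change falls below `tol` or `max_iter`
#' is reached. Clusters are read off the attractor structure; every node is
#' assigned to exactly one cluster (attractor overlap resolved by larger
#' flow, ties to the lexicographically smallest attractor).
#'
#' Self-loop weight is the maximum incident edge weight of the node (a
#' standard MCL regularisation); isolated nodes become singletons. The
#' computation is done per connected component, so the partition is
#' invariant under relabeling/permutation of the input.
#'
#' @param graph `data.frame(id_a, id_b, weight)` of undirected edges (no
#'   self-edges; weights in (0, 100] for identity-weighted graphs), or the
#'   output of [reciprocal_best_hits()] whose `global_identity` column is
#'   used as weight.
#' @param nodes optional character vector of all node ids, so that isolated
#'   nodes appear as singleton clusters.
#' @param inflation inflation exponent (> 1); default 2, the MCL default.
#' @param prune_threshold entries below this are set to zero each iteration.
#' @param max_iter,tol iteration cap and convergence threshold on the
#'   maximum absolute entry change.
#' @return Named integer vector: node id -> cluster id (1-based, numbered by
#'   the lexicographically smallest member).
#' @export
mcl_cluster <- function(graph, nodes = NULL, inflation = 2,
                        prune_threshold = 1e-5, max_iter = 200, tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (is.null(graph$weight) && !is.null(graph$global_identity))
    graph$weight <- graph$global_identity
  if (nrow(graph) > 0) {
    if (any(!is.finite(graph$weight))) stop("non-finite edge weights")
    if (any(graph$weight <= 0)) stop("edge weights must be positive")
    if (any(graph$id_a == graph$id_b)) stop("self-edges are not allowed")
  }
  all_nodes <- sort(unique(c(graph$id_a, graph$id_b, nodes)))
  if (length(all_nodes) == 0L) stop("empty graph")
  g <- igraph::graph_from_data_frame(
    graph[, c("id_a", "id_b", "weight")], directed = FALSE,
    vertices = data.frame(name = all_nodes))
  comp <- igraph::components(g)
  assignment <- integer(length(all_nodes))
  names(assignment) <- all_nodes
  next_id <- 1L
  for (ci in seq_len(comp$no)) {
    members <- sort(all_nodes[comp$membership == ci])
    if (length(members) == 1L) {
      assignment[members] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- graph[graph$id_a %in% members | graph$id_b %in% members, ,
                 drop = FALSE]
    labels <- mcl_component(members, sub, inflation, prune_threshold,
                            max_iter, tol)
    for (lab in unique(labels[order(match(names(labels), members))])) {
      assignment[names(labels)[labels == lab]] <- next_id
      next_id <- next_id + 1L
    }
  }
  # renumber clusters by lexicographically smallest member for determinism
  reps <- vapply(split(names(assignment), assignment), min, character(1))
  relabel <- stats::setNames(seq_along(sort(reps)), names(sort(reps)))
  out <- relabel[as.character(assignment)]
  names(out) <- names(assignment)
  out[all_nodes]
}

mcl_component <- function(members, edges, inflation, prune_threshold,
                          max_iter, tol) {
  n <- length(members)
  idx <- stats::setNames(seq_len(n), members)
  W <- matrix(0, n, n, dimnames = list(members, members))
  ia <- idx[edges$id_a]; ib <- idx[edges$id_b]
  for (k in seq_along(ia)) {
    W[ia[k], ib[k]] <- max(W[ia[k], ib[k]], edges$weight[k])
    W[ib[k], ia[k]] <- W[ia[k], ib[k]]
  }
  diag(W) <- apply(W, 1, max)
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  attractors <- which(diag(M) > tol)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  labels <- integer(n)
  for (j in seq_len(n)) {
    flow <- M[attractors, j]
    if (all(flow <= 0)) {
      labels[j] <- -j  # disconnected from any attractor: singleton
    } else {
      best <- max(flow)
      cand <- attractors[flow == best]
      labels[j] <- min(cand)  # tie -> lexicographically smallest attractor
    }
  }
  # merge attractor systems that share nodes is unnecessary: each node has
  # exactly one label; attractors sharing flow were resolved above
  stats::setNames(labels, members)
}

#' Split/join distance between two partitions
#'
#' van Dongen's split/join distance:
#' `2n - sum_A max_B |A & B| - sum_B max_A |A & B|`, where A and B range
#' over the clusters of the two partitions of the same n nodes.
#'
#' @param p1,p2 named cluster vectors over the same node set (as returned
#'   by [mcl_cluster()]).
#' @return Nonnegative integer; 0 iff the partitions are identical.
#' @export
split_join_distance <- function(p1, p2) {
  stopifnot(setequal(names(p1), names(p2)))
  p2 <- p2[names(p1)]
  tab <- table(p1, p2)
  2L * length(p1) - sum(apply(tab, 1, max)) - sum(apply(tab, 2, max))
}

#' Apply the family-size and species filters to a clustering
#'
#' Converts a partition of one domain's sequences into retained protein
#' families: prokaryotic (bacterial or archaeal) families must contain at
#' least `min_prok_seqs` sequences (default 5); eukaryotic families must be
#' present in at least `min_euk_species` species (default 2). Dropped
#' sequences are recorded in the `"dropped"` attribute.
#'
#' @param partition named cluster vector (sequence id -> cluster).
#' @param domain `"bacteria"`, `"archaea"` or `"eukaryote"`.
#' @param genome_map named character vector: sequence id -> genome id.
#' @param min_prok_seqs,min_euk_species the filter thresholds.
#' @return `data.frame(family_id, domain, seq_id, genome_id)`; attribute
#'   `"dropped"` holds the discarded sequence ids.
#' @export
filter_families <- function(partition, domain, genome_map,
                            min_prok_seqs = 5, min_euk_species = 2) {
  if (!domain %in% c("bacteria", "archaea", "eukaryote"))
    stop("unknown domain label: ", domain)
  if (!all(names(partition) %in% names(genome_map)))
    stop("every sequence must map to a genome")
  genomes <- genome_map[names(partition)]
  keep_cluster <- if (domain == "eukaryote") {
    nsp <- vapply(split(genomes, partition),
                  function(g) length(unique(g)), integer(1))
    names(nsp)[nsp >= min_euk_species]
  } else {
    sz <- table(partition)
    names(sz)[sz >= min_prok_seqs]
  }
  keep <- as.character(partition) %in% keep_cluster
  kept <- partition[keep]
  prefix <- c(bacteria = "bact", archaea = "arch", eukaryote = "euk")[domain]
  if (length(kept) == 0L) {
    out <- data.frame(family_id = character(0), domain = character(0),
                      seq_id = character(0), genome_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- sort(names(partition))
    return(out)
  }
  # deterministic family ids: clusters ordered by size desc, then smallest id
  cl_members <- split(names(kept), kept)
  ord <- order(-lengths(cl_members),
               vapply(cl_members, min, character(1)))
  cl_members <- cl_members[ord]
  fam_ids <- sprintf("%s_f%04d", prefix, seq_along(cl_members))
  out <- data.frame(
    family_id = rep(fam_ids, lengths(cl_members)),
    domain = domain,
    seq_id = unlist(cl_members, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$genome_id <- unname(genome_map[out$seq_id])
  attr(out, "dropped") <- sort(names(partition)[!keep])
  out
}
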