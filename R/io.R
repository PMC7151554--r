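#' Write a simulated dataset to disk
#'
#' One FASTA per genome (headers carry only the opaque sequence id; planted
#' truth lives in sidecar tables, never in the ids the pipeline sees), a
#' genome metadata TSV and the truth TSVs.
#'
#' @param sim an `"epc_simulation"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "epc_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fdir <- file.path(dir, "proteomes")
  dir.create(fdir, showWarnings = FALSE)
  mem <- sim$truth$members
  for (g in sim$genomes$genome_id) {
    ids <- mem$seq_id[mem$genome_id == g]
    Biostrings::writeXStringSet(sim$sequences[ids],
                                file.path(fdir, paste0(g, ".faa")))
  }
  write_tsv(sim$genomes, file.path(dir, "metadata.tsv"))
  write_tsv(sim$truth$families, file.path(dir, "truth_families.tsv"))
  write_tsv(sim$truth$members, file.path(dir, "truth_members.tsv"))
  invisible(dir)
}

#' Read a proteome directory
#'
#' Expects the layout written by [write_dataset()]: `proteomes/<genome>.faa`
#' plus `metadata.tsv` with genome_id, domain, genus, group, plastid,
#' parasite columns.
#'
#' @param dir dataset directory.
#' @return A list with `sequences` (named `AAStringSet`) and `genomes`.
#' @export
read_proteome_dir <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  seqs <- list()
  gmap <- character(0)
  for (g in meta$genome_id) {
    f <- file.path(dir, "proteomes", paste0(g, ".faa"))
    if (!file.exists(f)) stop("missing proteome file: ", f)
    s <- Biostrings::readAAStringSet(f)
    seqs[[g]] <- s
    gmap <- c(gmap, stats::setNames(rep(g, length(s)), names(s)))
  }
  sequences <- do.call(c, unname(seqs))
  list(sequences = sequences, genomes = meta, genome_map = gmap)
}

#' Read an ABC-format edge list
#'
#' Whitespace-separated `node_a node_b weight` lines, the interchange
#' format of MCL tooling.
#'
#' @param path file path.
#' @return `data.frame(id_a, id_b, weight)` suitable for [mcl_cluster()].
#' @export
read_abc_graph <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id_a", "id_b", "weight"))
  tab
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
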