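#' Stacked per-genome ancestry bars
#'
#' One stacked bar per eukaryote genome showing the mean bacterial (blue)
#' and archaeal (red) proportions over the downsampling replicates.
#'
#' @param estimates output of [estimate_proportions()].
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_ancestry_bars <- function(estimates, ...) {
  est <- estimates[!is.na(estimates$p_bacterial), , drop = FALSE]
  h <- rbind(archaeal = est$p_archaeal, bacterial = est$p_bacterial)
  colnames(h) <- est$genome_id
  graphics::barplot(h, col = c("firebrick", "steelblue"), border = NA,
                    las = 2, ylab = "proportion of genes",
                    legend.text = c("archaeal", "bacterial"), ...)
}

#' Raster view of the presence/absence matrix
#'
#' @param pam output of [presence_absence_matrix()].
#' @param ... passed to [graphics::image()].
#' @return `NULL`, invisibly.
#' @export
plot_presence_matrix <- function(pam, ...) {
  M <- pam$matrix
  graphics::image(t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE,
                  xlab = "EPCs (by eukaryotic group distribution)",
                  ylab = "genomes (taxonomic order)", ...)
  graphics::box()
  invisible(NULL)
}
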