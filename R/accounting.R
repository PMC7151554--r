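#' Accounting identities of the EPC pipeline
#'
#' The pipeline's bookkeeping ties the stage outputs together: the EPC total
#' is the sum of the bacterial-only, archaeal-only and dual counts; the
#' exclusive count is bacterial-only plus archaeal-only; the final count is
#' the exclusive count minus the recheck exclusions; eukaryote-specific
#' clusters are the eukaryotic families left after removing EPCs and
#' ambiguous clusters. Derived ratios: the bacterial fold excess
#' (bacterial-only / archaeal-only), the dual share of EPCs, the EPC share
#' of all eukaryotic clusters, and the share of eukaryotic
#' prokaryote-connected clusters whose origin call needs no phylogenetic
#' inference (non-dual EPCs).
#'
#' @param n_bacterial_only,n_archaeal_only,n_dual,n_ambiguous EPC counts by
#'   classification (pre-recheck).
#' @param n_recheck_excluded exclusive EPCs removed by the other-domain
#'   recheck.
#' @param n_euk_families total eukaryotic protein families.
#' @return A list of the derived quantities (see Details).
#' @export
epc_accounting <- function(n_bacterial_only, n_archaeal_only, n_dual,
                           n_ambiguous, n_recheck_excluded,
                           n_euk_families = NA_integer_) {
  n_epc <- n_bacterial_only + n_archaeal_only + n_dual
  n_exclusive <- n_bacterial_only + n_archaeal_only
  n_final <- n_exclusive - n_recheck_excluded
  list(
    n_epc = n_epc,
    n_exclusive = n_exclusive,
    n_final = n_final,
    n_euk_specific = if (is.na(n_euk_families)) NA_integer_
      else n_euk_families - n_epc - n_ambiguous,
    fold_excess_bacterial = n_bacterial_only / n_archaeal_only,
    pct_dual = 100 * n_dual / n_epc,
    pct_tree_independent = 100 * (n_epc - n_dual) / n_epc,
    pct_epc_of_euk_families = if (is.na(n_euk_families)) NA_real_
      else 100 * n_epc / n_euk_families)
}

#' Percentage-point gap between bacterial and archaeal proportions
#'
#' For genome-wide proportions `p_bacterial + p_archaeal = 1`, the excess of
#' bacterial over archaeal genes in percentage points (e.g. 0.56 vs 0.44
#' gives 12).
#'
#' @param p_bacterial,p_archaeal proportions in `[0, 1]`.
#' @return Numeric, percentage points.
#' @export
ancestry_gap <- function(p_bacterial, p_archaeal) {
  100 * (p_bacterial - p_archaeal)
}

# abort if the manifest counters violate the accounting identities
check_manifest_identities <- function(m) {
  ok1 <- m$n_epc == m$n_bacterial_only + m$n_archaeal_only + m$n_dual
  ok2 <- m$n_final == m$n_bacterial_only + m$n_archaeal_only -
    m$n_recheck_excluded
  if (!ok1 || !ok2)
    stop("accounting identity violated: n_epc=", m$n_epc,
         " b=", m$n_bacterial_only, " a=", m$n_archaeal_only,
         " dual=", m$n_dual, " final=", m$n_final,
         " recheck=", m$n_recheck_excluded)
  invisible(TRUE)
}
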