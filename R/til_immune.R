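#' Bin tumor-infiltrating-lymphocyte percentages
#'
#' Pathologist TIL scores (percent of all nuclei that are mononuclear
#' inflammatory cells) are binned as mild, moderate or intense. The
#' published band definitions (mild 0-10, moderate 20-40, intense >50)
#' leave 10-20 and 40-50 unassigned; half-open edges at 20 and 50 are used
#' so every score maps to exactly one bin: mild [0, 20), moderate [20, 50),
#' intense [50, 100].
#'
#' @param til_percent numeric vector in \[0, 100\].
#' @return factor with levels mild < moderate < intense.
#' @export
bin_til_levels <- function(til_percent) {
  til_percent <- as.numeric(til_percent)
  if (any(!is.finite(til_percent) | til_percent < 0 | til_percent > 100))
    stop("til_percent must lie in [0, 100]")
  cut(til_percent, breaks = c(-Inf, 20, 50, Inf), right = FALSE,
      labels = c("mild", "moderate", "intense"), ordered_result = TRUE)
}

#' Association between IM descriptor scores and lymphocytic infiltrate
#'
#' Quantifies how the immunomodulatory (IM) centroid correlation of each
#' tumor tracks its pathologist-scored TIL percentage: Spearman rank
#' correlation on the shared samples, per-bin median IM score after TIL
#' binning, a monotonicity flag (medians non-decreasing from mild to
#' intense), and a Kruskal-Wallis test of IM score across the three bins.
#'
#' When either variable is constant the rank correlation is undefined; the
#' result is flagged (`rho_defined = FALSE`) and the per-bin medians are
#' still returned.
#'
#' @param im_scores named numeric vector, `sample_id -> IM correlation`.
#' @param til data.frame with columns `sample_id`, `til_percent`.
#' @return list: `n`, `spearman_rho`, `rho_defined`, `bin_medians` (named
#'   mild/moderate/intense, NA for empty bins), `monotone`,
#'   `kruskal_p`.
#' @export
im_til_association <- function(im_scores, til) {
  stopifnot(!is.null(names(im_scores)), is.data.frame(til),
            all(c("sample_id", "til_percent") %in% names(til)))
  shared <- intersect(names(im_scores), as.character(til$sample_id))
  if (length(shared) == 0L) stop("no overlapping sample ids")
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  im <- im_scores[shared]
  tp <- til$til_percent[match(shared, til$sample_id)]
  rho_defined <- stats::sd(im) > 0 && stats::sd(tp) > 0
  rho <- if (rho_defined)
    stats::cor(im, tp, method = "spearman") else NA_real_
  bins <- bin_til_levels(tp)
  med <- tapply(im, bins, stats::median)
  med <- stats::setNames(as.numeric(med[levels(bins)]), levels(bins))
  present <- !is.na(med)
  monotone <- all(diff(med[present]) >= 0)
  kw_p <- if (nlevels(droplevels(bins)) >= 2L && stats::sd(im) > 0)
    stats::kruskal.test(im, bins)$p.value else NA_real_
  list(n = length(shared), spearman_rho = rho, rho_defined = rho_defined,
       bin_medians = med, monotone = monotone, kruskal_p = kw_p)
}
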