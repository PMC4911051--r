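#' Construct a centroid set
#'
#' A centroid set holds one weight vector per molecular subtype (genes in
#' rows, subtypes in columns, standardized log2 units) plus the names of the
#' tumor-intrinsic subtypes used by the four-subtype refinement
#' ([refine_tnbctype4()]). For the canonical six TNBC subtypes the intrinsic
#' subset is BL1, BL2, M and LAR; IM and MSL are treated as descriptors of
#' immune and stromal content.
#'
#' @param weights numeric matrix, gene ids as row names, subtype names as
#'   column names; each subtype needs at least 2 genes with finite weight.
#' @param intrinsic character vector of tumor-intrinsic subtype names;
#'   defaults to the intersection of the subtype names with
#'   c("BL1","BL2","M","LAR"), or all subtypes when that intersection is
#'   empty (e.g. a PAM50 centroid set passed through the same engine).
#' @return object of class `centroid_set` with elements `weights`,
#'   `subtypes`, `intrinsic`.
#' @export
centroid_set <- function(weights, intrinsic = NULL) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("centroid weights need gene row names and subtype column names")
  rownames(weights) <- normalize_gene_ids(rownames(weights))
  if (anyDuplicated(colnames(weights))) stop("duplicate subtype names")
  if (anyDuplicated(rownames(weights))) stop("duplicate centroid gene ids")
  n_ok <- colSums(is.finite(weights))
  if (any(n_ok < 2L))
    stop("each centroid needs >= 2 genes; offending: ",
         paste(colnames(weights)[n_ok < 2L], collapse = ", "))
  if (is.null(intrinsic)) {
    intrinsic <- intersect(colnames(weights), c("BL1", "BL2", "M", "LAR"))
    if (length(intrinsic) == 0L) intrinsic <- colnames(weights)
  }
  if (!all(intrinsic %in% colnames(weights)))
    stop("intrinsic subset must be a subset of subtype names")
  structure(list(weights = weights, subtypes = colnames(weights),
                 intrinsic = intrinsic),
            class = "centroid_set")
}

# canonical tie-break priority for the six TNBC subtypes
.tnbc_subtype_order <- c("BL1", "BL2", "IM", "M", "MSL", "LAR")

# order subtype names by the canonical priority, unknown names last in
# given order
order_subtypes <- function(names) {
  c(intersect(.tnbc_subtype_order, names),
    setdiff(names, .tnbc_subtype_order))
}

#' Correlate samples to subtype centroids
#'
#' For each sample and each centroid, computes the correlation (Spearman by
#' default) between the sample's expression and the centroid weights over
#' the genes shared by the matrix and that centroid. Errors if the shared
#' fraction of any centroid's genes falls below `min_overlap`.
#'
#' @param m expression matrix.
#' @param cs a [centroid_set()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_overlap minimum fraction of each centroid's genes that must be
#'   present in the matrix (default 0.5).
#' @return numeric matrix samples x subtypes of correlations, with an
#'   attribute `n_genes_used` (named integer vector per subtype).
#' @export
correlate_to_centroids <- function(m, cs, method = c("spearman", "pearson"),
                                   min_overlap = 0.5) {
  method <- match.arg(method)
  m <- expression_matrix(m)
  stopifnot(inherits(cs, "centroid_set"))
  corr <- matrix(NA_real_, ncol(m), length(cs$subtypes),
                 dimnames = list(colnames(m), cs$subtypes))
  n_used <- stats::setNames(integer(length(cs$subtypes)), cs$subtypes)
  for (s in cs$subtypes) {
    w <- cs$weights[, s]
    w <- w[is.finite(w)]
    shared <- intersect(names(w), rownames(m))
    if (length(shared) < min_overlap * length(w))
      stop(sprintf("centroid %s: only %d of %d genes present (min_overlap %.2f)",
                   s, length(shared), length(w), min_overlap))
    n_used[s] <- length(shared)
    corr[, s] <- suppressWarnings(
      stats::cor(m[shared, , drop = FALSE], w[shared], method = method))
  }
  attr(corr, "n_genes_used") <- n_used
  corr
}

#' Call six-way TNBC subtypes from centroid correlations
#'
#' Each sample is assigned the subtype with the highest correlation; exact
#' ties are broken by the fixed priority BL1 > BL2 > IM > M > MSL > LAR
#' (names outside the canonical six keep their column order, after the
#' canonical ones). Samples whose maximum correlation falls below
#' `uns_threshold` are unclassified (`UNS`). The IM and MSL correlations are
#' carried along as `im_score`/`msl_score` descriptors regardless of call.
#'
#' @param corr correlation matrix from [correlate_to_centroids()].
#' @param uns_threshold minimum correlation for a classified call
#'   (default 0.1).
#' @return data.frame with columns `sample_id`, `corr_<subtype>` for each
#'   subtype, `call6`, `im_score`, `msl_score`, `n_genes_used`.
#' @export
call_tnbctype <- function(corr, uns_threshold = 0.1) {
  stopifnot(is.matrix(corr), !is.null(colnames(corr)))
  if (anyNA(corr)) stop("missing correlation entries")
  ord <- order_subtypes(colnames(corr))
  cm <- corr[, ord, drop = FALSE]
  idx <- apply(cm, 1, which.max)          # first max wins -> fixed priority
  maxv <- cm[cbind(seq_len(nrow(cm)), idx)]
  call6 <- ifelse(maxv < uns_threshold, "UNS", colnames(cm)[idx])
  res <- data.frame(sample_id = rownames(corr), stringsAsFactors = FALSE)
  for (s in colnames(corr)) res[[paste0("corr_", s)]] <- corr[, s]
  res$call6 <- call6
  res$im_score <- if ("IM" %in% colnames(corr)) corr[, "IM"] else NA_real_
  res$msl_score <- if ("MSL" %in% colnames(corr)) corr[, "MSL"] else NA_real_
  n_used <- attr(corr, "n_genes_used")
  res$n_genes_used <- if (!is.null(n_used)) min(n_used) else NA_integer_
  res
}

#' Refine six-way calls to four tumor-intrinsic subtypes (TNBCtype-4)
#'
#' Samples called IM or MSL are reassigned to the highest-correlated
#' tumor-intrinsic centroid (BL1, BL2, M or LAR for the canonical set);
#' intrinsic calls pass through unchanged. This implements the
#' "second-highest centroid" reassignment while guaranteeing the refined
#' call space never contains IM or MSL even when those two occupy both top
#' ranks. Unclassified samples remain UNS unless their best intrinsic
#' correlation reaches `uns_threshold`. IM and MSL scores are untouched.
#'
#' @param res data.frame from [call_tnbctype()].
#' @param cs the [centroid_set()] used for calling (supplies the intrinsic
#'   subset).
#' @param uns_threshold as in [call_tnbctype()].
#' @return `res` with a `call4` column added.
#' @export
refine_tnbctype4 <- function(res, cs, uns_threshold = 0.1) {
  stopifnot(is.data.frame(res), "call6" %in% names(res),
            inherits(cs, "centroid_set"))
  intr <- order_subtypes(cs$intrinsic)
  cols <- paste0("corr_", intr)
  if (!all(cols %in% names(res)))
    stop("result lacks correlation columns for intrinsic subtypes")
  icorr <- as.matrix(res[, cols, drop = FALSE])
  best_i <- apply(icorr, 1, which.max)
  best_v <- icorr[cbind(seq_len(nrow(icorr)), best_i)]
  best_name <- intr[best_i]
  call4 <- res$call6
  nonintr <- !(res$call6 %in% c(intr, "UNS"))
  call4[nonintr] <- best_name[nonintr]
  uns <- res$call6 == "UNS"
  call4[uns] <- ifelse(best_v[uns] >= uns_threshold, best_name[uns], "UNS")
  res$call4 <- call4
  res
}

#' Full subtyping of an expression matrix
#'
#' Convenience wrapper: correlate, call six subtypes, refine to four.
#'
#' @inheritParams correlate_to_centroids
#' @inheritParams call_tnbctype
#' @return data.frame as from [refine_tnbctype4()].
#' @export
subtype_samples <- function(m, cs, method = "spearman", uns_threshold = 0.1,
                            min_overlap = 0.5) {
  corr <- correlate_to_centroids(m, cs, method, min_overlap)
  refine_tnbctype4(call_tnbctype(corr, uns_threshold), cs, uns_threshold)
}

#' Derive centroids from labeled samples
#'
#' Builds a centroid set empirically: each sample profile is standardized
#' across genes (zero mean, unit SD), then averaged per gene within each
#' label. Useful for constructing reference centroids from a labeled cohort
#' (the published centroid values are distributed separately and supplied
#' by the user). Profile standardization makes the centroids invariant to
#' per-sample location/scale shifts, matching how rank correlation consumes
#' them.
#'
#' @param m expression matrix.
#' @param labels named character vector or factor, `sample_id -> subtype`;
#'   every label needs at least 2 samples.
#' @param intrinsic passed to [centroid_set()].
#' @return a [centroid_set()].
#' @export
derive_centroids <- function(m, labels, intrinsic = NULL) {
  m <- expression_matrix(m)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by sample id")
  labels <- labels[intersect(names(labels), colnames(m))]
  tab <- table(labels)
  if (any(tab < 2L))
    stop("labels with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  z <- scale(m[, names(labels), drop = FALSE])
  z[!is.finite(z)] <- 0  # constant profiles carry no signal
  groups <- sort(unique(labels))
  w <- vapply(groups,
              function(g) rowMeans(z[, labels == g, drop = FALSE]),
              numeric(nrow(z)))
  colnames(w) <- groups
  centroid_set(w, intrinsic = intrinsic)
}
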