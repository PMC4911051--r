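#' Differential expression between two sample groups
#'
#' Per-gene two-sided t test (paired, or Welch for independent groups) on
#' log2 expression, with Benjamini-Hochberg adjustment across all tested
#' genes. A gene passes when |log2 fold change| >= log2(fc_cut) and the
#' BH q-value is below q_cut. Fold change is the difference of group means
#' on the log2 scale (so fc_cut = 2 requires |log2fc| >= 1); values are
#' never unlogged.
#'
#' With unpaired groups a variance floor guards genes whose within-group
#' variance is zero in both groups; such genes are flagged in
#' `var_floored`.
#'
#' @param m expression matrix.
#' @param group_a,group_b sample id vectors; for `paired = TRUE` they must
#'   have equal length and matched order.
#' @param paired paired t test on per-pair differences (default FALSE:
#'   Welch).
#' @param fc_cut fold-change gate on the natural scale (default 2).
#' @param q_cut BH q-value gate (default 0.01).
#' @param var_floor variance floor for degenerate Welch denominators.
#' @return data.frame: `gene_id`, `log2fc` (mean A - mean B), `statistic`,
#'   `p_value`, `q_value`, `passes`, `var_floored`.
#' @export
differential_expression <- function(m, group_a, group_b, paired = FALSE,
                                    fc_cut = 2, q_cut = 0.01,
                                    var_floor = 1e-8) {
  m <- expression_matrix(m)
  miss <- setdiff(c(group_a, group_b), colnames(m))
  if (length(miss)) stop("samples absent from matrix: ",
                         paste(miss, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 samples per group")
  A <- m[, group_a, drop = FALSE]
  B <- m[, group_b, drop = FALSE]
  log2fc <- rowMeans(A) - rowMeans(B)
  floored <- rep(FALSE, nrow(m))
  if (paired) {
    if (length(group_a) != length(group_b))
      stop("paired groups must have equal sizes and matched order")
    D <- A - B
    n <- ncol(D)
    sd_d <- apply(D, 1, stats::sd)
    sd_d <- pmax(sd_d, sqrt(var_floor))
    stat <- rowMeans(D) / (sd_d / sqrt(n))
    df <- rep(n - 1, nrow(m))
  } else {
    na <- ncol(A); nb <- ncol(B)
    va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
    floored <- va + vb < var_floor
    va <- pmax(va, var_floor / 2); vb <- pmax(vb, var_floor / 2)
    se2 <- va / na + vb / nb
    stat <- (rowMeans(A) - rowMeans(B)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  p <- 2 * stats::pt(-abs(stat), df)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(m), log2fc = log2fc, statistic = stat,
             p_value = p, q_value = q,
             passes = abs(log2fc) >= log2(fc_cut) & q < q_cut,
             var_floored = floored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation test of gene sets
#'
#' One-sided hypergeometric tail probability that a gene set overlaps the
#' differentially expressed genes at least as much as observed, given the
#' gene universe, with BH adjustment across sets. Sets are intersected with
#' the universe before testing.
#'
#' @param de_genes character vector of selected genes (must lie in
#'   `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all tested genes.
#' @return data.frame: `set`, `n_set` (after universe intersection),
#'   `overlap`, `p_value`, `q_value`.
#' @export
overrepresentation_test <- function(de_genes, gene_sets, universe) {
  universe <- unique(normalize_gene_ids(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  de_genes <- unique(normalize_gene_ids(de_genes))
  if (!all(de_genes %in% universe))
    stop("de_genes contains genes outside the universe")
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  N <- length(universe); k <- length(de_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(normalize_gene_ids(gene_sets[[nm]])), universe)
    ov <- length(intersect(set, de_genes))
    p <- stats::phyper(ov - 1, k, N - k, length(set), lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Concordance of subtype calls between matched tumor and stroma
#'
#' Compares the subtype call of each patient's microdissected tumor
#' epithelium with that of the adjacent stroma. A pair is discordant when
#' the two calls differ; discordant pairs whose stromal call is MSL are
#' counted separately, since stromal mesenchymal expression driving MSL
#' calls is the phenomenon of interest.
#'
#' @param pairs data.frame with columns `patient_id`, `tumor_call`,
#'   `stroma_call`.
#' @return list: `n_pairs`, `n_concordant`, `n_discordant`,
#'   `n_discordant_stroma_msl`, and `table` (the per-pair layout with a
#'   `concordant` flag).
#' @export
paired_subtype_concordance <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("patient_id", "tumor_call", "stroma_call") %in% names(pairs)))
  conc <- pairs$tumor_call == pairs$stroma_call
  disc_msl <- !conc & pairs$stroma_call == "MSL"
  tab <- data.frame(patient_id = pairs$patient_id,
                    tumor_call = pairs$tumor_call,
                    stroma_call = pairs$stroma_call,
                    concordant = conc, stringsAsFactors = FALSE)
  list(n_pairs = nrow(pairs),
       n_concordant = sum(conc),
       n_discordant = sum(!conc),
       n_discordant_stroma_msl = sum(disc_msl),
       table = tab)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test with an exact null for n <= 25 pairs:
#' the p-value is the probability, over all 2^n equiprobable sign
#' assignments of the absolute-difference ranks, of a positive-rank sum at
#' least as extreme as observed (smaller tail doubled, capped at 1). Zero
#' differences are dropped before ranking (Wilcoxon's original treatment)
#' and ties among |differences| receive midranks; the exact distribution is
#' computed on the realized rank multiset. Beyond 25 informative pairs a
#' normal approximation with continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list: `statistic` (W, sum of ranks where x > y), `p_value`,
#'   `n_used` (pairs after dropping zeros), `method` ("exact" or "normal"),
#'   `all_zero` flag.
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("non-finite paired differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "exact", all_zero = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of the positive-rank sum over all sign vectors, via
    # polynomial multiplication on doubled ranks (midranks -> integers)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- c(1, numeric(total))
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1 - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    W2 <- as.integer(round(2 * W))
    lower <- sum(probs[seq_len(W2 + 1)])           # P(W <= w)
    upper <- sum(probs[(W2 + 1):(total + 1)])      # P(W >= w)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_used = n, method = method,
       all_zero = FALSE)
}
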