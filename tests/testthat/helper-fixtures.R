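# shared fixture builders -------------------------------------------------

# tiny expression matrix with known values
make_expr <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 3 else length(genes))
  rownames(m) <- if (is.null(genes)) paste0("G", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) paste0("S", seq_len(ncol(m))) else samples
  m
}

# the bundled ten matched tumor/stroma LCM subtype-call pairs
lcm_pair_calls <- function() {
  path <- system.file("extdata", "lcm_pair_calls.tsv", package = "tnbctype4")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# receptor mixture fits for a cohort's marker rows
fit_marker_mixtures <- function(expr, seed = 100L,
                                markers = c("ESR1", "PGR", "ERBB2")) {
  stats::setNames(lapply(seq_along(markers), function(k)
    fit_mixture_1d(expr[markers[k], ], seed = seed + k,
                   marker = markers[k])), markers)
}

# brute-force Spearman for vectors without ties: 1 - 6*sum(d^2)/(n^3 - n)
spearman_no_ties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n^3 - n)
}

# exact two-sided signed-rank p by full enumeration over sign vectors
signed_rank_enum <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}
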