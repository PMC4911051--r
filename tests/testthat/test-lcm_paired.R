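test_that("identical groups yield no differential genes", {
  co <- generate_paired_lcm(n_pairs = 4, n_genes = 100, seed = 2)
  ids <- co$pairs$tumor_sample
  de <- differential_expression(co$expression, ids, ids, paired = FALSE)
  expect_equal(sum(de$passes), 0L)
  expect_true(all(abs(de$log2fc) < 1e-12))
})

test_that("spiked genes are detected and null genes are not", {
  sim <- generate_paired_lcm(n_pairs = 10, n_genes = 500, n_spiked = 50,
                             compartment_fc = 2, stroma_msl_boost = 0,
                             noise_sd = 0.3, seed = 5)
  de <- differential_expression(sim$expression, sim$pairs$tumor_sample,
                                sim$pairs$stroma_sample, paired = TRUE)
  spiked <- de$gene_id %in% sim$spiked$gene_id
  expect_gte(sum(de$passes & spiked), 45)
  expect_lte(sum(de$passes & !spiked), 1)
})

test_that("fold-change gate blocks significant genes below the cut", {
  set.seed(6)
  n <- 40
  # one gene shifted by 0.9 log2 units with tiny noise: p minuscule, FC < 2
  vals <- rbind(sub = c(rnorm(n, 0.9, 0.01), rnorm(n, 0, 0.01)),
                null = rnorm(2 * n, 0, 0.01))
  colnames(vals) <- paste0("s", seq_len(2 * n))
  de <- differential_expression(expression_matrix(vals),
                                paste0("s", 1:n), paste0("s", n + 1:n))
  row <- de[de$gene_id == "SUB", ]
  expect_lt(row$p_value, 1e-10)
  expect_false(row$passes)
})

test_that("BH q-values respect the p-value ordering", {
  co <- generate_paired_lcm(n_pairs = 5, n_genes = 200, seed = 9)
  de <- differential_expression(co$expression, co$pairs$tumor_sample,
                                co$pairs$stroma_sample, paired = TRUE)
  ord <- order(de$p_value)
  expect_true(all(diff(de$q_value[ord]) >= -1e-12))
  expect_true(all(de$q_value >= de$p_value - 1e-12))
  # independent oracle: textbook step-up computation
  m <- nrow(de)
  oracle <- rev(cummin(rev(de$p_value[ord] * m / seq_len(m))))
  expect_equal(de$q_value[ord], pmin(oracle, 1))
})

test_that("per-gene type-I error is controlled under the global null", {
  set.seed(77)
  hits <- 0L; total <- 0L
  for (rep_i in 1:200) {
    vals <- matrix(rnorm(50 * 10), 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
    de <- differential_expression(vals, paste0("s", 1:5), paste0("s", 6:10))
    hits <- hits + sum(de$p_value < 0.05)
    total <- total + nrow(de)
  }
  expect_gte(hits / total, 0.03)
  expect_lte(hits / total, 0.07)
})

test_that("over-representation p-values match combinatorial enumeration", {
  universe <- paste0("u", 1:20)
  de <- universe[1:5]
  sets <- list(hit = universe[1:5],        # full overlap
               none = universe[6:10],      # disjoint
               all = universe)             # the whole universe
  res <- overrepresentation_test(de, sets, universe)
  expect_equal(res$overlap[res$set == "none"], 0L)
  expect_equal(res$p_value[res$set == "none"], 1)
  expect_equal(res$p_value[res$set == "all"], 1)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5))

  # enumeration oracle for a partial overlap
  set.seed(3)
  s <- sample(universe, 8)
  res2 <- overrepresentation_test(de, list(s = s), universe)
  k <- length(intersect(s, de))
  # P(overlap >= k) by direct hypergeometric sum
  oracle <- sum(vapply(k:5, function(i)
    choose(8, i) * choose(12, 5 - i), numeric(1))) / choose(20, 5)
  expect_equal(res2$p_value, oracle)
  expect_error(overrepresentation_test(de, sets, character(0)), "empty")
  expect_error(overrepresentation_test(c(de, "zz"), sets, universe),
               "outside")
})

test_that("tumor/stroma concordance counts match the bundled ten pairs", {
  pairs <- lcm_pair_calls()
  res <- paired_subtype_concordance(pairs)
  expect_equal(res$n_pairs, 10L)
  expect_equal(res$n_discordant, 6L)
  expect_equal(res$n_concordant, 4L)
  expect_equal(res$n_discordant_stroma_msl, 5L)
  expect_equal(sum(res$table$concordant), 4L)
})

test_that("concordance counting agrees with hand enumeration", {
  set.seed(14)
  subs <- c("BL1", "BL2", "M", "LAR", "MSL")
  pairs <- data.frame(patient_id = paste0("p", 1:7),
                      tumor_call = sample(subs, 7, TRUE),
                      stroma_call = sample(subs, 7, TRUE))
  res <- paired_subtype_concordance(pairs)
  disc <- 0L; disc_msl <- 0L
  for (i in 1:7) {
    if (pairs$tumor_call[i] != pairs$stroma_call[i]) {
      disc <- disc + 1L
      if (pairs$stroma_call[i] == "MSL") disc_msl <- disc_msl + 1L
    }
  }
  expect_equal(res$n_discordant, disc)
  expect_equal(res$n_discordant_stroma_msl, disc_msl)
  same <- pairs; same$stroma_call <- same$tumor_call
  expect_equal(paired_subtype_concordance(same)$n_discordant, 0L)
})

test_that("exact signed-rank test reproduces analytic cases", {
  # ten pairs, all differences positive -> 2/2^10
  res <- wilcoxon_signed_rank_exact(2:11 + 0.1 * (1:10), 2:11)
  expect_equal(res$p_value, 2 / 1024)
  expect_equal(res$statistic, 55)
  # one up one down of equal magnitude -> symmetric, p = 1
  res2 <- wilcoxon_signed_rank_exact(c(1, 2), c(0, 3))
  expect_equal(res2$p_value, 1)
  # all-zero differences
  res3 <- wilcoxon_signed_rank_exact(c(1, 2, 3), c(1, 2, 3))
  expect_true(res3$all_zero)
  expect_equal(res3$p_value, 1)
})

test_that("exact signed-rank p matches full sign-vector enumeration", {
  set.seed(8)
  for (rep_i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(wilcoxon_signed_rank_exact(x, y)$p_value,
                 signed_rank_enum(x, y))
  }
  # with ties among |differences| (midranks) the DP must match enumeration
  x <- c(3, 1, 4, 1, 5); y <- c(2, 2, 3, 0, 3)   # |d| = 1,1,1,1,2
  expect_equal(wilcoxon_signed_rank_exact(x, y)$p_value,
               signed_rank_enum(x, y))
  # cross-check against the standard exact test when no zeros/ties
  x2 <- c(1.3, 2.1, -0.5, 4.2, 0.7, -1.1, 2.9, 3.3)
  y2 <- c(0.9, 2.8, 0.1, 3.0, 1.5, -0.2, 1.1, 2.2)
  expect_equal(wilcoxon_signed_rank_exact(x2, y2)$p_value,
               wilcox.test(x2, y2, paired = TRUE, exact = TRUE)$p.value)
})

test_that("signed-rank p is invariant to rank-preserving transforms and swaps", {
  set.seed(19)
  x <- rnorm(8); y <- rnorm(8)
  base <- wilcoxon_signed_rank_exact(x, y)$p_value
  # monotone transform of the difference magnitudes, signs kept
  d <- x - y
  d2 <- sign(d) * (abs(d)^3 + abs(d))
  expect_equal(wilcoxon_signed_rank_exact(d2, rep(0, 8))$p_value, base)
  expect_equal(wilcoxon_signed_rank_exact(y, x)$p_value, base)
})

test_that("compartments separate in principal component space", {
  skip_if_not_installed("cluster")
  sim <- generate_paired_lcm(n_pairs = 8, n_genes = 300, compartment_fc = 2,
                             stroma_msl_boost = 1, noise_sd = 0.3, seed = 12)
  pc <- prcomp(t(sim$expression), center = TRUE, scale. = FALSE)
  labels <- rep(c(1L, 2L), each = 8)   # tumor then stroma columns
  sil <- cluster::silhouette(labels, dist(pc$x[, 1, drop = FALSE]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
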