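make_centroids <- function(n_genes = 20, seed = 1) {
  generate_centroids(n_genes = max(n_genes, 50), seed = seed)$centroids
}

test_that("correlation to centroids hits the analytic extremes", {
  cs <- make_centroids(seed = 4)
  w <- cs$weights[, "BL1"]
  m <- cbind(match = w, rev = -w)
  rownames(m) <- names(w)
  corr <- correlate_to_centroids(expression_matrix(m), cs)
  expect_equal(unname(corr["match", "BL1"]), 1)
  expect_equal(unname(corr["rev", "BL1"]), -1)
  expect_equal(unname(attr(corr, "n_genes_used")[["BL1"]]), nrow(m))
})

test_that("spearman correlation matches the explicit rank formula", {
  set.seed(11)
  w <- rnorm(5)
  cs <- centroid_set(matrix(c(w, rnorm(5)), 5,
                            dimnames = list(paste0("g", 1:5), c("A", "B"))))
  x <- rnorm(5)
  m <- make_expr(x, genes = paste0("g", 1:5), samples = "s1")
  corr <- correlate_to_centroids(m, cs)
  expect_equal(unname(corr["s1", "A"]), spearman_no_ties(x, w))
})

test_that("insufficient gene overlap raises a descriptive error", {
  cs <- make_centroids(seed = 4)
  m <- make_expr(rnorm(10 * 2), genes = rownames(cs$weights)[1:10])
  expect_error(correlate_to_centroids(m, cs), "min_overlap")
})

test_that("six-way calls use argmax, UNS threshold and fixed tie order", {
  subtypes <- c("BL1", "BL2", "IM", "M", "MSL", "LAR")
  corr <- matrix(c(0.6, 0.2, 0.1, 0.15, 0.05, 0.1,   # BL1 wins
                   0.05, 0.09, 0.02, 0.0, -0.1, 0.08, # all < 0.1 -> UNS
                   0.1, 0.5, 0.2, 0.5, 0.3, 0.1),     # BL2 = M tie
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("s1", "s2", "s3"), subtypes))
  res <- call_tnbctype(corr)
  expect_equal(res$call6, c("BL1", "UNS", "BL2"))
  expect_equal(res$im_score, unname(corr[, "IM"]))
  expect_error(call_tnbctype(corr[, -3, drop = FALSE]), NA) # subsets allowed
  corr_na <- corr; corr_na[1, 2] <- NA
  expect_error(call_tnbctype(corr_na), "missing")
})

test_that("TNBCtype-4 refinement reassigns IM/MSL to intrinsic subtypes", {
  subtypes <- c("BL1", "BL2", "IM", "M", "MSL", "LAR")
  cs <- make_centroids(seed = 4)
  corr <- matrix(c(0.5, 0.2, 0.7, 0.2, 0.1, 0.0,   # IM top, BL1 best intrinsic
                   0.1, 0.2, 0.7, 0.5, 0.6, 0.0,   # IM, MSL both above M
                   0.6, 0.1, 0.2, 0.1, 0.0, 0.0,   # intrinsic call passes through
                   0.05, 0.0, 0.3, 0.02, 0.0, 0.0),# UNS, intrinsic all < 0.1
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("s", 1:4), subtypes))
  res <- refine_tnbctype4(call_tnbctype(corr), cs)
  expect_equal(res$call6, c("IM", "IM", "BL1", "IM"))
  expect_equal(res$call4[1], "BL1")
  # literal second-highest would be MSL; intrinsic max M must win
  expect_equal(res$call4[2], "M")
  expect_equal(res$call4[3], "BL1")
  expect_equal(res$call4[4], "BL1") # IM call reassigned even when intrinsic
                                    # correlations are weak
  # IM/MSL descriptor scores unchanged by refinement
  expect_equal(res$im_score, unname(corr[, "IM"]))
  expect_equal(res$msl_score, unname(corr[, "MSL"]))
})

test_that("refinement is the identity on cohorts without IM/MSL calls", {
  co <- generate_cohort(cohort_config(n_samples = 60, seed = 8))
  sub <- subtype_samples(co$expression[-(1:3), ], co$centroids)
  no_imsl <- sub$call6 %in% c("BL1", "BL2", "M", "LAR", "UNS")
  expect_equal(sub$call4[no_imsl & sub$call6 != "UNS"],
               sub$call6[no_imsl & sub$call6 != "UNS"])
  # call4 never IM or MSL, anywhere
  expect_false(any(sub$call4 %in% c("IM", "MSL")))
})

test_that("calls are invariant to strictly monotone sample transforms", {
  co <- generate_cohort(cohort_config(n_samples = 30, seed = 15))
  m <- co$expression[-(1:3), ]
  sub1 <- subtype_samples(m, co$centroids)
  m2 <- exp(m / 4) + 1          # strictly monotone, highly nonlinear
  sub2 <- subtype_samples(expression_matrix(m2), co$centroids)
  expect_equal(sub1$call6, sub2$call6)
  expect_equal(sub1$call4, sub2$call4)
  expect_equal(sub1$im_score, sub2$im_score)
})

test_that("subtype recovery is accurate and degrades with noise", {
  accs <- vapply(c(0.5, 1, 2, 4, 8), function(noise) {
    co <- generate_cohort(cohort_config(n_samples = 200, noise_sd = noise,
                                        seed = 31))
    sub <- subtype_samples(co$expression[-(1:3), ], co$centroids)
    mean(sub$call4 == co$truth$subtype)
  }, numeric(1))
  expect_gte(accs[2], 0.95)            # default noise_sd = 1
  expect_true(all(diff(accs) <= 0.02)) # essentially monotone decay
  expect_gt(accs[1], accs[5])
})

test_that("IM and M descriptor scores anti-correlate under immune admixture", {
  co <- generate_cohort(cohort_config(n_samples = 400, seed = 23))
  sub <- subtype_samples(co$expression[-(1:3), ], co$centroids)
  expect_lt(cor(sub$im_score, sub$corr_M, method = "spearman"), 0)
})

test_that("derived centroids recover the generating structure", {
  m <- make_expr(rep(c(1, 5, 2, 8), 2), genes = paste0("g", 1:4),
                 samples = c("a", "b"))
  dc <- derive_centroids(m, setNames(c("X", "X"), c("a", "b")),
                         intrinsic = "X")
  # two identical samples -> centroid equals their standardized profile
  prof <- as.numeric(scale(m[, "a"]))
  expect_equal(unname(dc$weights[, "X"]), prof)

  co <- generate_cohort(cohort_config(n_samples = 300, seed = 3))
  dc2 <- derive_centroids(co$expression[-(1:3), ],
                          setNames(co$truth$subtype, co$truth$sample_id))
  cc <- diag(cor(dc2$weights, co$centroids$weights[, colnames(dc2$weights)]))
  expect_true(all(cc >= 0.9))

  # relabeling permutes centroid columns identically
  lab <- setNames(co$truth$subtype, co$truth$sample_id)
  perm <- c(BL1 = "Q1", BL2 = "Q2", M = "Q3", LAR = "Q4")
  dc3 <- derive_centroids(co$expression[-(1:3), ], setNames(perm[lab], names(lab)),
                          intrinsic = unname(perm))
  expect_equal(unname(dc3$weights[, perm["M"]]), unname(dc2$weights[, "M"]))

  expect_error(derive_centroids(m, setNames(c("X", "Y"), c("a", "b"))),
               "fewer than 2")
})
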