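test_that("chi-square equals the closed form and handles edge tables", {
  # closed-form oracle on random 4x3 tables
  set.seed(2)
  for (rep_i in 1:10) {
    tab <- matrix(rpois(12, 20) + 1, 4, 3)
    res <- contingency_test(tab, "chisq")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E))
    expect_equal(res$df, 6L)
    expect_equal(res$p_value, pchisq(sum((tab - E)^2 / E), 6, lower.tail = FALSE))
  }
  # proportional rows carry no association
  tab0 <- rbind(c(10, 20, 30), c(5, 10, 15))
  res0 <- contingency_test(tab0, "chisq")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_warning(contingency_test(rbind(c(3, 4), c(0, 0), c(5, 6)), "chisq"),
                 "zero-margin")
})

test_that("fisher 2x2 p matches hypergeometric enumeration", {
  fisher_enum <- function(tab) {
    # sum the probabilities of all tables with the observed margins whose
    # conditional probability does not exceed the observed one
    r <- rowSums(tab); c_ <- colSums(tab); n <- sum(tab)
    a_range <- max(0, r[1] - c_[2]):min(r[1], c_[1])
    probs <- dhyper(a_range, c_[1], c_[2], r[1])
    p_obs <- dhyper(tab[1, 1], c_[1], c_[2], r[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  expect_equal(contingency_test(matrix(c(3, 1, 1, 3), 2), "fisher")$p_value,
               fisher_enum(matrix(c(3, 1, 1, 3), 2)))
  set.seed(5)
  for (rep_i in 1:20) {
    n <- sample(8:40, 1)
    tab <- matrix(rmultinom(1, n, runif(4, 0.1, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(contingency_test(tab, "fisher")$p_value, fisher_enum(tab),
                 tolerance = 1e-10)
  }
})

test_that("auto method selects fisher only for sparse 2x2 tables", {
  sparse <- matrix(c(2, 8, 7, 3), 2)
  expect_equal(contingency_test(sparse, "auto")$method, "fisher")
  dense <- matrix(c(20, 30, 25, 25), 2)
  expect_equal(contingency_test(dense, "auto")$method, "chisq")
})

test_that("odds ratios versus the whole cohort behave arithmetically", {
  o <- odds_ratio_vs_cohort(list(n_pcr = 45, n_total = 110),
                            list(n_pcr = 101, n_total = 306))
  expect_equal(o$or, (45 / 65) / (101 / 205))
  expect_lt(o$ci_low, o$or); expect_gt(o$ci_high, o$or)
  # group equal to cohort -> exactly 1
  same <- odds_ratio_vs_cohort(list(n_pcr = 30, n_total = 100),
                               list(n_pcr = 30, n_total = 100))
  expect_equal(same$or, 1)
  # zero cell handled by continuity correction
  z <- odds_ratio_vs_cohort(list(n_pcr = 0, n_total = 20),
                            list(n_pcr = 100, n_total = 300))
  expect_true(is.finite(z$or) && z$or > 0)
  # monotone in group successes, all else fixed
  ors <- vapply(5:15, function(k)
    odds_ratio_vs_cohort(list(n_pcr = k, n_total = 40),
                         list(n_pcr = 100, n_total = 300))$or, numeric(1))
  expect_true(all(diff(ors) > 0))
  expect_error(odds_ratio_vs_cohort(list(n_pcr = 0, n_total = 0),
                                    list(n_pcr = 1, n_total = 2)), "positive")
})

test_that("binomial intervals match their defining formulas", {
  expect_equal(binomial_ci(0, 10, "clopper_pearson")[1], 0)
  expect_equal(binomial_ci(10, 10, "clopper_pearson")[2], 100)
  # Wilson closed form evaluated independently
  z <- qnorm(0.975); p <- 45 / 110; n <- 110
  low <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  high <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(binomial_ci(45, 110, "wilson"), 100 * c(low, high))
})

test_that("Kaplan-Meier estimates match hand product-limit computation", {
  k <- km_fit(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(summary(k$fit)$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(k$medians), 2)
  # no events: flat survival, median undefined
  k0 <- km_fit(c(1, 2, 3), c(0, 0, 0), rep("g", 3))
  expect_true(all(summary(k0$fit, times = c(1, 2, 3))$surv == 1))
  expect_true(is.na(unname(k0$medians)))
  # without censoring KM equals the empirical survival function
  set.seed(4)
  t_ <- rexp(50)
  k1 <- km_fit(t_, rep(1, 50), rep("g", 50))
  s <- summary(k1$fit)
  emp <- vapply(s$time, function(tt) mean(t_ > tt), numeric(1))
  expect_equal(s$surv, emp)
})

test_that("logrank is null for identical groups and powered for distinct ones", {
  k <- km_fit(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(k$logrank_stat, 0)
  expect_equal(k$logrank_p, 1)
  set.seed(10)
  t1 <- rexp(100, 0.05); t2 <- rexp(100, 0.3)
  k2 <- km_fit(c(t1, t2), rep(1, 200), rep(c("a", "b"), each = 100))
  expect_lt(k2$logrank_p, 1e-6)
  expect_equal(logrank_each_vs_rest(c(t1, t2), rep(1, 200),
                                    rep(c("a", "b"), each = 100), "a"),
               k2$logrank_p)
})

test_that("Cox regression recovers a known hazard coefficient", {
  set.seed(13)
  n <- 500
  x <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(0.5 * x))
  cens <- runif(n, 0, 15)
  fit <- cox_continuous(x, pmin(t_ev, cens), as.integer(t_ev <= cens))
  expect_lt(abs(fit$beta - 0.5), 0.15)
  expect_lt(fit$lrt_p, 1e-6)
  # reparameterization: scaling the covariate by k scales beta by 1/k
  fit2 <- cox_continuous(3 * x, pmin(t_ev, cens), as.integer(t_ev <= cens))
  expect_equal(fit2$beta, fit$beta / 3, tolerance = 1e-6)
  expect_error(cox_continuous(rep(1, n), t_ev, rep(1, n)), "constant")
})

test_that("the subtype outcome report assembles consistent statistics", {
  co <- generate_cohort(cohort_config(n_samples = 800, seed = 17))
  clin <- co$clinical[co$truth$is_tnbc, ]
  clin$subtype <- co$truth$subtype[co$truth$is_tnbc]
  rep_ <- subtype_outcome_report(clin)
  tab <- rep_$pcr_table
  # per-group rates near configured values, within the binomial envelope
  rates <- c(BL1 = 0.41, BL2 = 0.18, M = 0.35, LAR = 0.29)
  for (g in tab$group) {
    envelope <- qbinom(c(0.025, 0.975), tab$n[tab$group == g], rates[[g]])
    expect_gte(tab$n_pcr[tab$group == g], envelope[1])
    expect_lte(tab$n_pcr[tab$group == g], envelope[2])
  }
  # survival section: each endpoint has each-vs-rest p per group
  expect_true(all(c("os", "rfs", "drfs") %in% names(rep_$survival)))
  expect_length(rep_$survival$os$each_vs_rest, 4L)

  # null cohort: shared pCR rate -> ORs near 1
  clin0 <- clin
  set.seed(1); clin0$pcr <- rbinom(nrow(clin0), 1, 0.3)
  tab0 <- subtype_outcome_report(clin0)$pcr_table
  expect_true(all(abs(log(tab0$or)) < log(2)))

  # single-subtype cohort reduces the OR to exactly 1
  clin1 <- clin[clin$subtype == "BL1", ]
  tab1 <- subtype_outcome_report(clin1)$pcr_table
  expect_equal(tab1$or, 1)
})
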