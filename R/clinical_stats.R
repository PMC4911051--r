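#' Contingency test for categorical associations
#'
#' Pearson chi-square (no continuity correction) or Fisher's exact test on
#' an r x c count table. `method = "auto"` uses Fisher for 2 x 2 tables with
#' any expected cell below 5, otherwise the chi-square. Rows or columns with
#' zero margin are dropped with a warning before testing.
#'
#' @param table matrix of non-negative integer counts.
#' @param method `"auto"`, `"chisq"` or `"fisher"` (fisher requires 2 x 2
#'   after margin dropping).
#' @return list: `observed`, `statistic` (chi-square; NA for fisher), `df`,
#'   `p_value`, `method`.
#' @export
contingency_test <- function(table, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2x2 table after dropping empty margins")
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (all(dim(tab) == 2L) && any(expected < 5)) "fisher" else "chisq"
  }
  if (method == "fisher") {
    if (!all(dim(tab) == 2L)) stop("fisher method requires a 2x2 table")
    p <- stats::fisher.test(tab)$p.value
    res <- list(observed = tab, statistic = NA_real_, df = NA_integer_,
                p_value = p, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(observed = tab, statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value,
                method = "chisq")
  }
  res
}

#' Odds ratio of a subgroup's pCR against the whole cohort
#'
#' Odds ratio of achieving pathological complete response in a subtype
#' group relative to the entire unselected cohort (which may include the
#' group itself, matching how subgroup forest plots against the full cohort
#' are drawn; the comparison is therefore not independent). The
#' Haldane-Anscombe 0.5 correction is applied when any of the four cells is
#' zero, and the 95% CI is the Woolf log-scale interval.
#'
#' @param group list or vector with `n_pcr`, `n_total` for the group.
#' @param cohort same for the reference cohort.
#' @param label optional group label.
#' @param conf_level confidence level (default 0.95).
#' @return list: `label`, `or`, `ci_low`, `ci_high`, and the cell counts
#'   `a` (group pCR), `b` (group RD), `c` (cohort pCR), `d` (cohort RD).
#' @export
odds_ratio_vs_cohort <- function(group, cohort, label = NA_character_,
                                 conf_level = 0.95) {
  a <- group[["n_pcr"]]; b <- group[["n_total"]] - a
  c_ <- cohort[["n_pcr"]]; d <- cohort[["n_total"]] - c_
  if (group[["n_total"]] <= 0 || cohort[["n_total"]] <= 0)
    stop("n_total must be positive")
  if (min(a, b, c_, d) < 0) stop("negative cell count")
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(label = label, or = or,
       ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       a = a, b = b, c = c_, d = d)
}

#' Binomial confidence interval on the percentage scale
#'
#' Two-sided interval for a binomial proportion, reported on the 0-100
#' scale. `wilson` is the score interval; `clopper_pearson` is the exact
#' interval (lower bound exactly 0 at 0 successes, upper exactly 100 at n
#' successes).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n >= 1`.
#' @param method `"wilson"` (default) or `"clopper_pearson"`.
#' @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(low, high)` in percent.
#' @export
binomial_ci <- function(successes, n, method = c("wilson", "clopper_pearson"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n >= 1, successes >= 0, successes <= n)
  if (method == "clopper_pearson") {
    ci <- stats::binom.test(successes, n, conf.level = conf_level)$conf.int
    return(100 * as.numeric(ci))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  100 * c(max(0, center - half), min(1, center + half))
}

#' Kaplan-Meier fit with logrank comparison
#'
#' Product-limit survival estimate per group with a standard logrank test
#' across groups (score test of `survival::survdiff`). The median is the
#' first time at which the estimated survival drops to 0.5 or below
#' (NA when never reached).
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups group labels (at least one subject per group). A single
#'   group yields curves but no logrank test is possible; requesting one
#'   errors.
#' @return list: `fit` (a `survfit` object), `groups`, `medians` (named),
#'   `logrank_stat`, `logrank_df`, `logrank_p` (NA with a single group).
#' @export
km_fit <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  df <- data.frame(time = times, event = events,
                   group = factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  med <- summary(fit)$table
  if (is.null(dim(med))) {
    medians <- stats::setNames(med[["median"]], levels(df$group))
  } else {
    medians <- stats::setNames(med[, "median"],
                               sub("^group=", "", rownames(med)))
  }
  if (nlevels(df$group) < 2L) {
    return(list(fit = fit, groups = levels(df$group), medians = medians,
                logrank_stat = NA_real_, logrank_df = NA_integer_,
                logrank_p = NA_real_))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  df_lr <- length(sd_$n) - 1L
  list(fit = fit, groups = levels(df$group), medians = medians,
       logrank_stat = unname(sd_$chisq), logrank_df = df_lr,
       logrank_p = stats::pchisq(sd_$chisq, df_lr, lower.tail = FALSE))
}

#' Logrank test of one group against all others pooled
#'
#' @param times,events as in [km_fit()].
#' @param groups group labels.
#' @param target the group compared against the pooled rest.
#' @return logrank p-value (unadjusted).
#' @export
logrank_each_vs_rest <- function(times, events, groups, target) {
  g2 <- ifelse(groups == target, target, "rest")
  if (length(unique(g2)) < 2L) stop("target group is the whole cohort")
  km_fit(times, events, g2)$logrank_p
}

#' Cox regression on a continuous covariate
#'
#' Proportional-hazards fit of survival on one continuous covariate (e.g.
#' the IM correlation score) with Breslow tie handling; significance by the
#' likelihood ratio test against the null model on 1 df.
#'
#' @param covariate numeric per-sample covariate (non-constant).
#' @param times,events survival outcome.
#' @param min_events minimum number of events required (default 10).
#' @return list: `beta`, `se`, `hr` (per unit covariate), `lrt_stat`,
#'   `lrt_p`, `n`, `n_events`.
#' @export
cox_continuous <- function(covariate, times, events, min_events = 10L) {
  stopifnot(length(covariate) == length(times),
            length(times) == length(events))
  ok <- is.finite(covariate) & is.finite(times) & !is.na(events)
  covariate <- covariate[ok]; times <- times[ok]; events <- events[ok]
  if (stats::sd(covariate) == 0)
    stop("constant covariate is non-identifiable")
  if (sum(events) < min_events)
    stop("need at least ", min_events, " events, got ", sum(events))
  fit <- survival::coxph(survival::Surv(times, events) ~ covariate,
                         ties = "breslow")
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  beta <- unname(stats::coef(fit))
  list(beta = beta, se = sqrt(unname(diag(fit$var))), hr = exp(beta),
       lrt_stat = lrt, lrt_p = stats::pchisq(lrt, 1, lower.tail = FALSE),
       n = length(times), n_events = sum(events))
}

#' Subtype-stratified clinical outcome report
#'
#' Assembles the per-subtype clinical statistics for a cohort table:
#' per-group pCR rate with binomial CI, odds ratio of pCR against the whole
#' unselected cohort (forest-plot-ready), an overall chi-square across
#' groups, Kaplan-Meier curves and logrank tests per survival endpoint, and
#' unadjusted each-vs-rest logrank p-values per group. Groups with fewer
#' than `min_group` subjects with response data are excluded from the
#' OR/CI table with a warning.
#'
#' @param cohort clinical data.frame (see [read_clinical()]); must contain
#'   the grouping column, and `pcr` (0/1/NA) for response statistics;
#'   survival endpoints `os`/`rfs`/`drfs` are used where the corresponding
#'   `<endpoint>_time`/`<endpoint>_event` columns exist.
#' @param by name of the grouping column (default `"subtype"`).
#' @param ci_method passed to [binomial_ci()].
#' @param min_group minimum group size for OR/CI inclusion (default 5).
#' @return list: `pcr_table` (group, n, n_pcr, rate_pct, ci_low, ci_high,
#'   or, or_low, or_high), `cohort_rate_pct`, `pcr_contingency`
#'   (overall test across groups), `excluded_groups`, `survival` (per
#'   endpoint: `km` from [km_fit()] plus `each_vs_rest` named p-values).
#' @export
subtype_outcome_report <- function(cohort, by = "subtype",
                                   ci_method = "wilson", min_group = 5L) {
  stopifnot(is.data.frame(cohort), by %in% names(cohort))
  groups <- as.character(cohort[[by]])

  pcr_table <- NULL
  pcr_contingency <- NULL
  cohort_rate <- NA_real_
  excluded <- character(0)
  if ("pcr" %in% names(cohort)) {
    has_pcr <- !is.na(cohort$pcr)
    pcr <- cohort$pcr[has_pcr]
    g <- groups[has_pcr]
    coh <- list(n_pcr = sum(pcr), n_total = length(pcr))
    cohort_rate <- 100 * coh$n_pcr / coh$n_total
    tab <- table(g, factor(pcr, levels = c(1, 0)))
    if (nrow(tab) >= 2L)
      pcr_contingency <- contingency_test(unclass(tab), method = "chisq")
    rows <- lapply(sort(unique(g)), function(grp) {
      n <- sum(g == grp); np <- sum(pcr[g == grp])
      if (n < min_group) return(data.frame(group = grp, n = n, n_pcr = np,
                                           rate_pct = NA_real_,
                                           ci_low = NA_real_, ci_high = NA_real_,
                                           or = NA_real_, or_low = NA_real_,
                                           or_high = NA_real_))
      ci <- binomial_ci(np, n, method = ci_method)
      orr <- odds_ratio_vs_cohort(list(n_pcr = np, n_total = n), coh,
                                  label = grp)
      data.frame(group = grp, n = n, n_pcr = np, rate_pct = 100 * np / n,
                 ci_low = ci[1], ci_high = ci[2], or = orr$or,
                 or_low = orr$ci_low, or_high = orr$ci_high)
    })
    pcr_table <- do.call(rbind, rows)
    excluded <- pcr_table$group[is.na(pcr_table$rate_pct)]
    if (length(excluded))
      warning("groups with < ", min_group,
              " responses excluded from OR/CI: ",
              paste(excluded, collapse = ", "))
  }

  surv <- list()
  for (ep in c("os", "rfs", "drfs")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(cohort))) next
    ok <- !is.na(cohort[[tcol]]) & !is.na(cohort[[ecol]])
    if (sum(ok) < 2L || length(unique(groups[ok])) < 2L) next
    km <- km_fit(cohort[[tcol]][ok], cohort[[ecol]][ok], groups[ok])
    evr <- vapply(km$groups, function(grp)
      logrank_each_vs_rest(cohort[[tcol]][ok], cohort[[ecol]][ok],
                           groups[ok], grp), numeric(1))
    surv[[ep]] <- list(km = km, each_vs_rest = evr)
  }

  list(pcr_table = pcr_table, cohort_rate_pct = cohort_rate,
       pcr_contingency = pcr_contingency, excluded_groups = excluded,
       survival = surv)
}
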