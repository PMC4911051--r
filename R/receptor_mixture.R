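#' Fit a two-component Gaussian mixture to one marker
#'
#' Models the across-sample distribution of a single receptor transcript
#' (e.g. ESR1, PGR or ERBB2 on the log2 scale) as a mixture of a "negative"
#' and a "positive" expressing population and fits it by
#' expectation-maximization from several starts, keeping the best
#' log-likelihood. Components are relabeled so that `mu_neg <= mu_pos`.
#'
#' The fit is flagged `unimodal_flag` when the component means are closer
#' than one pooled standard deviation or either mixing weight falls below
#' 0.05; such markers carry no usable bimodal signal and downstream calling
#' treats them conservatively (see [call_receptor_status()]).
#'
#' @param values numeric vector of log2 expression across samples
#'   (at least 10 finite values).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param n_init number of starts: one quantile-based plus `n_init - 1`
#'   seeded random starts.
#' @param seed integer seed controlling the random starts.
#' @param marker optional marker name recorded in the fit.
#' @param var_floor variance floor applied to both components (log2 scale).
#' @return object of class `mixture_fit`: a list with elements `marker`,
#'   `mu_neg`, `mu_pos`, `sigma_neg`, `sigma_pos`, `w_neg`, `w_pos`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `unimodal_flag`.
#' @export
fit_mixture_1d <- function(values, tol = 1e-8, max_iter = 500L, n_init = 5L,
                           seed = 1L, marker = NA_character_,
                           var_floor = 1e-4) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values in mixture input")
  n <- length(values)
  if (n < 10L) stop("need at least 10 values to fit a mixture, got ", n)

  if (stats::sd(values) < sqrt(var_floor)) {
    # degenerate: essentially constant input, no mixture structure
    mu <- mean(values)
    fit <- list(marker = marker, mu_neg = mu, mu_pos = mu,
                sigma_neg = sqrt(var_floor), sigma_pos = sqrt(var_floor),
                w_neg = 0.5, w_pos = 0.5, loglik = NA_real_,
                loglik_trace = numeric(0), n_iter = 0L,
                converged = FALSE, unimodal_flag = TRUE)
    class(fit) <- "mixture_fit"
    return(fit)
  }

  starts <- list(list(mu = stats::quantile(values, c(0.25, 0.75), names = FALSE),
                      sigma = rep(stats::sd(values) / 2, 2),
                      w = c(0.5, 0.5)))
  if (n_init > 1L) {
    rng <- local({set.seed(as.integer(seed)); lapply(seq_len(n_init - 1L), function(i) {
      mu <- sort(sample(values, 2L))
      list(mu = mu, sigma = rep(max(stats::sd(values) * stats::runif(1, 0.3, 1), sqrt(var_floor)), 2),
           w = {w1 <- stats::runif(1, 0.2, 0.8); c(w1, 1 - w1)})
    })})
    starts <- c(starts, rng)
  }

  best <- NULL
  for (s in starts) {
    fit <- em_gauss2(values, s$mu, s$sigma, s$w, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # relabel so the lower-mean component is "negative"
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$sigma <- rev(best$sigma); best$w <- rev(best$w)
  }
  pooled_sd <- sqrt(sum(best$w * best$sigma^2))
  unimodal <- (best$mu[2] - best$mu[1]) < pooled_sd || min(best$w) < 0.05

  fit <- list(marker = marker,
              mu_neg = best$mu[1], mu_pos = best$mu[2],
              sigma_neg = best$sigma[1], sigma_pos = best$sigma[2],
              w_neg = best$w[1], w_pos = best$w[2],
              loglik = best$loglik, loglik_trace = best$trace,
              n_iter = best$n_iter, converged = best$converged,
              unimodal_flag = unimodal)
  class(fit) <- "mixture_fit"
  fit
}

# EM core for a 1-D two-component Gaussian mixture.
em_gauss2 <- function(x, mu, sigma, w, tol, max_iter, var_floor) {
  n <- length(x)
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll; converged <- TRUE; break
    }
    loglik <- ll
    r1 <- d1 / tot
    r2 <- 1 - r1
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-10 || n2 < 1e-10) break  # a component collapsed
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                         sum(r2 * (x - mu[2])^2) / n2), var_floor))
  }
  list(mu = mu, sigma = sigma, w = w, loglik = loglik, trace = trace,
       n_iter = iter, converged = converged)
}

#' Posterior probability of membership in the negative component
#'
#' Standard mixture responsibility of the low-mean component at each value.
#'
#' @param fit a `mixture_fit`.
#' @param x numeric vector of log2 expression.
#' @return numeric vector in \[0, 1\].
#' @export
posterior_negative <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  d_neg <- fit$w_neg * stats::dnorm(x, fit$mu_neg, fit$sigma_neg)
  d_pos <- fit$w_pos * stats::dnorm(x, fit$mu_pos, fit$sigma_pos)
  tot <- d_neg + d_pos
  tot[tot == 0] <- .Machine$double.xmin
  d_neg / tot
}

#' Call per-sample receptor status and the TNBC flag
#'
#' For each marker, computes the posterior probability that a sample belongs
#' to the negative-expression component of the fitted mixture and calls the
#' marker negative when that posterior reaches `threshold`. A sample is
#' triple-negative (`is_tnbc`) when all markers are called negative.
#'
#' Markers whose fit is flagged unimodal carry no reliable negative/positive
#' split; they are called positive for every sample (posterior set to 0)
#' with a warning, which conservatively prevents spurious triple-negative
#' calls.
#'
#' @param m expression matrix containing one row per marker.
#' @param fits named list of `mixture_fit` objects, names = marker gene ids.
#' @param threshold posterior-negative threshold for a negative call
#'   (default 0.5).
#' @return data.frame with `sample_id`, per-marker `<marker>_post_neg` and
#'   `<marker>_status` columns, and `is_tnbc`.
#' @export
call_receptor_status <- function(m, fits, threshold = 0.5) {
  m <- expression_matrix(m)
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  markers <- normalize_gene_ids(names(fits))
  missing <- setdiff(markers, rownames(m))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  neg <- matrix(NA, ncol(m), length(markers))
  for (k in seq_along(markers)) {
    fit <- fits[[k]]
    x <- m[markers[k], ]
    if (isTRUE(fit$unimodal_flag)) {
      warning("marker ", markers[k],
              " has a unimodal fit; calling all samples positive")
      post <- rep(0, length(x))
    } else {
      post <- posterior_negative(fit, x)
    }
    neg[, k] <- post >= threshold
    out[[paste0(tolower(markers[k]), "_post_neg")]] <- post
    out[[paste0(tolower(markers[k]), "_status")]] <-
      ifelse(neg[, k], "negative", "positive")
  }
  out$is_tnbc <- apply(neg, 1, all)
  out
}

#' Identify TNBC samples, optionally combined with IHC annotation
#'
#' @param calls data.frame from [call_receptor_status()].
#' @param ihc optional data.frame with columns `sample_id` and `ihc_tnbc`
#'   (logical triple-negative status by immunohistochemistry; NA allowed).
#' @param rule how to combine mixture and IHC calls: `mixture_only`
#'   (default; IHC ignored), `ihc_and` (both must call triple-negative),
#'   `ihc_rescue` (mixture call used wherever available, IHC fills in
#'   samples without a usable mixture call).
#' @return sorted, duplicate-free character vector of TNBC sample ids.
#' @export
identify_tnbc <- function(calls, ihc = NULL,
                          rule = c("mixture_only", "ihc_and", "ihc_rescue")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(calls), nrow(calls) > 0L,
            all(c("sample_id", "is_tnbc") %in% names(calls)))
  mix <- stats::setNames(calls$is_tnbc, calls$sample_id)
  if (rule == "mixture_only" || is.null(ihc)) {
    keep <- names(mix)[mix %in% TRUE]
    return(sort(unique(keep)))
  }
  stopifnot(all(c("sample_id", "ihc_tnbc") %in% names(ihc)))
  path <- stats::setNames(ihc$ihc_tnbc, ihc$sample_id)
  ids <- names(mix)
  p <- path[ids]
  keep <- switch(rule,
    ihc_and = (mix %in% TRUE) & (p %in% TRUE),
    ihc_rescue = ifelse(is.na(mix), p %in% TRUE, mix %in% TRUE))
  sort(unique(ids[keep]))
}

#' TNBC percentage from counts
#'
#' Cohort-summary arithmetic: the percentage of samples called
#' triple-negative, rounded to one decimal as reported in dataset summary
#' tables (e.g. 182 of 508 gives 35.8).
#'
#' @param n_tnbc number of TNBC samples.
#' @param n_total total samples.
#' @return percentage on the 0-100 scale, one decimal.
#' @export
tnbc_percentage <- function(n_tnbc, n_total) {
  stopifnot(n_total > 0, n_tnbc >= 0, n_tnbc <= n_total)
  round(100 * n_tnbc / n_total, 1)
}
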