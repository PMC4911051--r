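#' Cohort simulation configuration
#'
#' Assembles and validates the parameters of the synthetic TNBC cohort
#' generator. Defaults describe a neoadjuvant-style cohort: 30% of samples
#' triple-negative, four tumor-intrinsic subtypes at proportions
#' 0.36/0.22/0.25/0.17 (BL1/BL2/M/LAR), receptor marker mixtures separated
#' by 5 within-component SDs (clean bimodality), convex additive immune and
#' stromal admixture with Beta(2, 5) per-sample weights, a TIL percentage
#' rank-correlated 0.67 with the immune admixture, per-subtype pCR
#' probabilities 0.41/0.18/0.35/0.29, and per-subtype exponential survival
#' hazards with uniform censoring.
#'
#' @param n_samples cohort size.
#' @param tnbc_fraction probability a sample is triple-negative.
#' @param subtype_proportions named numeric over BL1/BL2/M/LAR, summing
#'   to 1.
#' @param mu_neg,mu_pos,sigma_neg,sigma_pos receptor mixture component
#'   parameters (log2 units), shared across the three markers.
#' @param marker_neg_prob marginal probability each single marker is
#'   negative in a non-TNBC sample (redrawn if all three come out
#'   negative).
#' @param n_genes number of signature genes (>= 50).
#' @param signal_sd SD multiplier of the subtype centroid signal.
#' @param noise_sd SD of per-gene Gaussian noise.
#' @param admix_strength multiplier on the admixture signatures.
#' @param admix_shape1,admix_shape2 Beta parameters of the per-sample
#'   immune and stromal admixture weights.
#' @param im_til_rho target Spearman correlation between immune admixture
#'   and TIL percentage (Gaussian copula).
#' @param pcr_rates named per-subtype pCR probabilities.
#' @param pcr_rate_nontnbc pCR probability for non-TNBC samples.
#' @param hazards named per-subtype exponential event hazards (per year).
#' @param hazard_nontnbc hazard for non-TNBC samples.
#' @param censor_max upper bound of uniform censoring times (years).
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 500L,
                          tnbc_fraction = 0.30,
                          subtype_proportions = c(BL1 = 0.36, BL2 = 0.22,
                                                  M = 0.25, LAR = 0.17),
                          mu_neg = 5, mu_pos = 10,
                          sigma_neg = 1, sigma_pos = 1,
                          marker_neg_prob = 0.4,
                          n_genes = 500L,
                          signal_sd = 1, noise_sd = 1,
                          admix_strength = 1,
                          admix_shape1 = 2, admix_shape2 = 5,
                          im_til_rho = 0.67,
                          pcr_rates = c(BL1 = 0.41, BL2 = 0.18,
                                        M = 0.35, LAR = 0.29),
                          pcr_rate_nontnbc = 0.15,
                          hazards = c(BL1 = 0.06, BL2 = 0.20,
                                      M = 0.13, LAR = 0.10),
                          hazard_nontnbc = 0.08,
                          censor_max = 10,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              tnbc_fraction = tnbc_fraction,
              subtype_proportions = subtype_proportions,
              mu_neg = mu_neg, mu_pos = mu_pos,
              sigma_neg = sigma_neg, sigma_pos = sigma_pos,
              marker_neg_prob = marker_neg_prob,
              n_genes = as.integer(n_genes),
              signal_sd = signal_sd, noise_sd = noise_sd,
              admix_strength = admix_strength,
              admix_shape1 = admix_shape1, admix_shape2 = admix_shape2,
              im_til_rho = im_til_rho,
              pcr_rates = pcr_rates, pcr_rate_nontnbc = pcr_rate_nontnbc,
              hazards = hazards, hazard_nontnbc = hazard_nontnbc,
              censor_max = censor_max, seed = as.integer(seed))
  if (cfg$n_samples < 1L) stop("config: n_samples must be positive")
  if (cfg$tnbc_fraction < 0 || cfg$tnbc_fraction > 1)
    stop("config: tnbc_fraction must lie in [0, 1]")
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-8)
    stop("config: subtype_proportions must sum to 1")
  if (is.null(names(cfg$subtype_proportions)))
    stop("config: subtype_proportions must be named")
  if (cfg$n_genes < 50L) stop("config: n_genes must be >= 50")
  if (any(cfg$pcr_rates < 0 | cfg$pcr_rates > 1) ||
      cfg$pcr_rate_nontnbc < 0 || cfg$pcr_rate_nontnbc > 1)
    stop("config: pCR rates must lie in [0, 1]")
  if (!setequal(names(cfg$pcr_rates), names(cfg$subtype_proportions)) ||
      !setequal(names(cfg$hazards), names(cfg$subtype_proportions)))
    stop("config: pcr_rates and hazards must be named per subtype")
  if (any(cfg$hazards <= 0) || cfg$hazard_nontnbc <= 0)
    stop("config: hazards must be positive")
  if (cfg$sigma_neg <= 0 || cfg$sigma_pos <= 0)
    stop("config: mixture sigmas must be positive")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate subtype centroids plus immune and stromal signatures
#'
#' Produces near-orthogonal centroid weight vectors (one per subtype) by
#' orthonormalizing a Gaussian matrix, plus two admixture signatures: an
#' immune signature built with a positive loading on the IM centroid and a
#' negative loading on the M centroid (correlation with M about -0.6,
#' emulating the observed antagonism between immune infiltrate and the
#' mesenchymal expression state), and a stromal signature loading on the
#' MSL centroid. All vectors are scaled to unit SD. Deterministic given the
#' seed.
#'
#' @param n_genes number of genes (>= 50).
#' @param subtype_names centroid names; defaults to the canonical six.
#' @param seed integer seed.
#' @return list: `centroids` (a [centroid_set()]), `immune_sig`,
#'   `stromal_sig` (named numeric vectors), `gene_ids`.
#' @export
generate_centroids <- function(n_genes = 500L,
                               subtype_names = c("BL1", "BL2", "IM", "M",
                                                 "MSL", "LAR"),
                               seed = 1L) {
  stopifnot(n_genes >= 50L, length(subtype_names) >= 2L)
  set.seed(as.integer(seed))
  k <- length(subtype_names)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  # orthonormal basis: k centroid directions + 2 signature residuals
  Q <- qr.Q(qr(matrix(stats::rnorm(n_genes * (k + 2L)), n_genes)))
  unit_sd <- function(v) v / stats::sd(v)
  W <- apply(Q[, seq_len(k), drop = FALSE], 2, unit_sd)
  dimnames(W) <- list(gene_ids, subtype_names)
  u <- function(name) if (name %in% subtype_names)
    Q[, match(name, subtype_names)] else Q[, k + 1L]
  imm <- 0.5 * u("IM") - 0.6 * u("M") + sqrt(1 - 0.5^2 - 0.6^2) * Q[, k + 1L]
  str <- 0.8 * u("MSL") + 0.6 * Q[, k + 2L]
  immune_sig <- stats::setNames(unit_sd(imm), gene_ids)
  stromal_sig <- stats::setNames(unit_sd(str), gene_ids)
  list(centroids = centroid_set(W), immune_sig = immune_sig,
       stromal_sig = stromal_sig, gene_ids = gene_ids)
}

# markers carried as extra expression rows by the cohort generator
.tnbc_markers <- c("ESR1", "PGR", "ERBB2")

#' Generate a synthetic TNBC cohort
#'
#' Emulates the statistical structure the downstream analyses assume:
#' expression is subtype centroid signal plus convex additive immune and
#' stromal admixture plus Gaussian noise; ESR1/PGR/ERBB2 rows are drawn
#' from the two-component receptor mixture according to the sample's true
#' TNBC status (non-TNBC samples have at least one positive marker); TIL
#' percentages are generated with a Gaussian copula so their Spearman
#' correlation with the immune admixture targets `im_til_rho`; pCR is
#' Bernoulli with per-subtype rates; survival is exponential with
#' per-subtype hazards and independent uniform censoring. Pure function of
#' the configuration (which includes the seed).
#'
#' @param cfg a [cohort_config()].
#' @return list: `expression` (markers + signature genes by samples),
#'   `truth` (sample_id, is_tnbc, subtype, immune_w, stroma_w, marker
#'   statuses), `clinical` (see [read_clinical()] columns), `til`
#'   (sample_id, til_percent), `centroids`, `immune_sig`, `stromal_sig`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  sig <- generate_centroids(cfg$n_genes, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  subtypes <- names(cfg$subtype_proportions)
  sample_ids <- sprintf("S%04d", seq_len(n))

  is_tnbc <- stats::runif(n) < cfg$tnbc_fraction
  subtype <- sample(subtypes, n, replace = TRUE,
                    prob = cfg$subtype_proportions)
  w_imm <- stats::rbeta(n, cfg$admix_shape1, cfg$admix_shape2)
  w_str <- stats::rbeta(n, cfg$admix_shape1, cfg$admix_shape2)

  W <- sig$centroids$weights
  E <- cfg$signal_sd * W[, subtype, drop = FALSE] +
    cfg$admix_strength * (outer(sig$immune_sig, w_imm) +
                          outer(sig$stromal_sig, w_str)) +
    matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd), cfg$n_genes)
  colnames(E) <- sample_ids

  # receptor marker rows: TNBC samples are negative for all three markers;
  # non-TNBC samples draw each marker, conditioned on not all-negative
  neg_status <- matrix(TRUE, n, 3L,
                       dimnames = list(sample_ids, .tnbc_markers))
  for (i in which(!is_tnbc)) {
    repeat {
      s <- stats::runif(3) < cfg$marker_neg_prob
      if (!all(s)) break
    }
    neg_status[i, ] <- s
  }
  M <- t(apply(neg_status, 1, function(s)
    stats::rnorm(3, ifelse(s, cfg$mu_neg, cfg$mu_pos),
                 ifelse(s, cfg$sigma_neg, cfg$sigma_pos))))
  marker_rows <- t(M)
  rownames(marker_rows) <- .tnbc_markers

  expr <- expression_matrix(rbind(marker_rows, E))

  # TIL percent rank-correlated with the immune admixture weight
  z1 <- stats::qnorm(stats::pbeta(w_imm, cfg$admix_shape1, cfg$admix_shape2))
  r <- 2 * sin(pi * cfg$im_til_rho / 6)   # copula r for target Spearman rho
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  til_percent <- 100 * stats::qbeta(stats::pnorm(z2), 1.2, 8)

  pcr_rate <- ifelse(is_tnbc, cfg$pcr_rates[subtype], cfg$pcr_rate_nontnbc)
  pcr <- as.integer(stats::runif(n) < pcr_rate)
  hazard <- ifelse(is_tnbc, cfg$hazards[subtype], cfg$hazard_nontnbc)
  surv_ep <- function(mult) {
    t_event <- stats::rexp(n, hazard * mult)
    t_cens <- stats::runif(n, 0, cfg$censor_max)
    list(time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
  }
  os <- surv_ep(1); rfs <- surv_ep(1.5); drfs <- surv_ep(1.3)

  clinical <- data.frame(
    sample_id = sample_ids,
    subtype = ifelse(is_tnbc, subtype, "nonTNBC"),
    pcr = pcr,
    age = round(stats::rnorm(n, 53, 11), 1),
    grade = sample(1:3, n, replace = TRUE, prob = c(0.03, 0.2, 0.77)),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.17, 0.65, 0.16, 0.02)),
    node_positive = as.integer(stats::runif(n) < 0.33),
    tumor_size_mm = round(stats::rlnorm(n, log(25), 0.35), 1),
    met_brain = as.integer(stats::runif(n) < 0.11),
    met_bone = as.integer(stats::runif(n) < 0.19),
    met_lung = as.integer(stats::runif(n) < 0.31),
    os_time = os$time, os_event = os$event,
    rfs_time = rfs$time, rfs_event = rfs$event,
    drfs_time = drfs$time, drfs_event = drfs$event,
    im_score = z1,
    stringsAsFactors = FALSE)

  truth <- data.frame(sample_id = sample_ids, is_tnbc = is_tnbc,
                      subtype = subtype, immune_w = w_imm, stroma_w = w_str,
                      esr1_neg = neg_status[, "ESR1"],
                      pgr_neg = neg_status[, "PGR"],
                      erbb2_neg = neg_status[, "ERBB2"],
                      stringsAsFactors = FALSE)

  list(expression = expr, truth = truth, clinical = clinical,
       til = data.frame(sample_id = sample_ids, til_percent = til_percent,
                        stringsAsFactors = FALSE),
       centroids = sig$centroids, immune_sig = sig$immune_sig,
       stromal_sig = sig$stromal_sig)
}

#' Generate matched tumor/stroma profile pairs
#'
#' Emulates laser-capture microdissection pairs: each patient contributes a
#' tumor-epithelium profile (subtype centroid signal plus a shared
#' patient-level effect plus noise) and a matched stroma profile that
#' additionally receives `stroma_msl_boost` times the stromal signature
#' (which loads on the MSL centroid) and a compartment fold change on the
#' spiked genes (half elevated in tumor, half in stroma, `compartment_fc`
#' on the log2 scale).
#'
#' @param n_pairs number of patients (>= 2).
#' @param n_genes number of genes.
#' @param n_spiked number of compartment-differential genes.
#' @param compartment_fc log2 fold change applied to spiked genes.
#' @param stroma_msl_boost multiplier of the stromal signature added to
#'   stroma profiles.
#' @param noise_sd per-gene noise SD.
#' @param patient_sd SD of the shared patient-level effect.
#' @param signal_sd subtype signal SD.
#' @param seed integer seed.
#' @return list: `expression` (genes by 2*n_pairs samples, columns
#'   T1..S1..), `pairs` (patient_id, tumor_sample, stroma_sample, subtype),
#'   `spiked` (gene_id, log2fc_tumor_vs_stroma), `centroids`,
#'   `stromal_sig`.
#' @export
generate_paired_lcm <- function(n_pairs = 10L, n_genes = 500L,
                                n_spiked = 50L, compartment_fc = 2,
                                stroma_msl_boost = 1, noise_sd = 0.3,
                                patient_sd = 0.5, signal_sd = 1,
                                seed = 1L) {
  stopifnot(n_pairs >= 2L, n_spiked <= n_genes)
  sig <- generate_centroids(n_genes, seed = seed)
  set.seed(as.integer(seed) + 1L)
  W <- sig$centroids$weights
  intr <- sig$centroids$intrinsic
  subtype <- sample(intr, n_pairs, replace = TRUE)

  spiked_idx <- sample(n_genes, n_spiked)
  direction <- rep(c(1, -1), length.out = n_spiked)  # + = up in tumor
  spike_vec <- numeric(n_genes)
  spike_vec[spiked_idx] <- direction * compartment_fc

  tumor <- matrix(NA_real_, n_genes, n_pairs)
  stroma <- matrix(NA_real_, n_genes, n_pairs)
  for (i in seq_len(n_pairs)) {
    base <- signal_sd * W[, subtype[i]] +
      stats::rnorm(n_genes, sd = patient_sd)
    tumor[, i] <- base + spike_vec / 2 +
      stats::rnorm(n_genes, sd = noise_sd)
    stroma[, i] <- base - spike_vec / 2 +
      stroma_msl_boost * sig$stromal_sig +
      stats::rnorm(n_genes, sd = noise_sd)
  }
  tumor_ids <- sprintf("T%02d", seq_len(n_pairs))
  stroma_ids <- sprintf("S%02d", seq_len(n_pairs))
  expr <- cbind(tumor, stroma)
  dimnames(expr) <- list(sig$gene_ids, c(tumor_ids, stroma_ids))

  list(expression = expression_matrix(expr),
       pairs = data.frame(patient_id = sprintf("P%02d", seq_len(n_pairs)),
                          tumor_sample = tumor_ids,
                          stroma_sample = stroma_ids,
                          subtype = subtype, stringsAsFactors = FALSE),
       spiked = data.frame(gene_id = sig$gene_ids[spiked_idx],
                           log2fc_tumor_vs_stroma = direction * compartment_fc,
                           stringsAsFactors = FALSE),
       centroids = sig$centroids, stromal_sig = sig$stromal_sig)
}
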