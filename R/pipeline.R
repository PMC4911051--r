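#' Run the full subtyping analysis pipeline
#'
#' Orchestrates the stages in fixed order: (1) simulate a cohort or ingest
#' user files, (2) fit receptor mixtures and call TNBC status, (3)
#' correlate to centroids, call six subtypes and refine to TNBCtype-4,
#' (4) assemble the subtype-stratified clinical report. All randomness
#' flows from the single configuration seed (per-stage seeds are derived by
#' fixed offsets). Each output directory receives exactly one
#' `manifest.json` recording the configuration echo, input file hashes,
#' seed, package version, per-stage row counts and timestamps.
#'
#' Configuration is a YAML file (or an equivalent named list) with keys:
#' \describe{
#'   \item{seed}{integer, required.}
#'   \item{simulate}{optional list of [cohort_config()] overrides; when
#'     present the cohort is generated.}
#'   \item{inputs}{otherwise required: paths `expression`, `centroids`,
#'     and optionally `clinical`, `til`.}
#'   \item{thresholds}{optional: `posterior` (0.5), `uns` (0.1),
#'     `min_overlap` (0.5), `ci_method` ("wilson").}
#'   \item{markers}{receptor marker gene ids (default ESR1, PGR, ERBB2).}
#' }
#'
#' Schema violations signal a condition of class `tnbc_config_error`;
#' missing input files signal `tnbc_input_error`; stage failures are
#' prefixed with the stage name.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return (invisibly) the output directory path. Writes
#'   `receptor_calls.csv`, `subtypes.csv`, `pcr_report.csv`,
#'   `report.json` and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config))
      stop(tnbc_error("tnbc_input_error", paste0("config file not found: ", config)))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop(tnbc_error("tnbc_config_error", "config must be a list or YAML path"))
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop(tnbc_error("tnbc_config_error", "config field 'seed' (integer) is required"))
  seed <- as.integer(config$seed)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir))
    stop(tnbc_error("tnbc_config_error", "config field 'out_dir' is required"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  thr <- utils::modifyList(
    list(posterior = 0.5, uns = 0.1, min_overlap = 0.5,
         ci_method = "wilson"),
    if (is.null(config$thresholds)) list() else config$thresholds)
  markers <- if (is.null(config$markers)) c("ESR1", "PGR", "ERBB2")
             else as.character(config$markers)

  counts <- list()
  hashes <- list()

  # stage 1: simulate or ingest -------------------------------------------
  stage <- "simulate"
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.list(sim_args))
      stop(tnbc_error("tnbc_config_error", "config field 'simulate' must be a mapping"))
    sim_args$seed <- seed
    cfg <- tryCatch(do.call(cohort_config, sim_args),
                    error = function(e) stop(tnbc_error("tnbc_config_error",
                      paste0("simulate: ", conditionMessage(e)))))
    cohort <- generate_cohort(cfg)
    expr <- cohort$expression
    centroids <- cohort$centroids
    clinical <- cohort$clinical
    til <- cohort$til
  } else {
    stage <- "ingest"
    inp <- config$inputs
    if (is.null(inp) || is.null(inp$expression) || is.null(inp$centroids))
      stop(tnbc_error("tnbc_config_error",
        "config requires either 'simulate' or 'inputs' with 'expression' and 'centroids'"))
    for (f in unlist(inp)) if (!file.exists(f))
      stop(tnbc_error("tnbc_input_error", paste0("input file not found: ", f)))
    hashes <- lapply(inp, function(f) unname(tools::md5sum(f)))
    expr <- read_expression(inp$expression,
                            dialect = if (grepl("\\.csv$", inp$expression)) "csv" else "tsv")
    centroids <- read_centroids(inp$centroids,
                                dialect = if (grepl("\\.csv$", inp$centroids)) "csv" else "tsv")
    clinical <- if (!is.null(inp$clinical)) read_clinical(inp$clinical) else NULL
    til <- if (!is.null(inp$til))
      utils::read.csv(inp$til, stringsAsFactors = FALSE) else NULL
  }
  counts$samples <- ncol(expr)
  counts$genes <- nrow(expr)

  # stage 2: receptor mixtures and TNBC calls ------------------------------
  stage <- "receptors"
  fits <- tryCatch(
    stats::setNames(lapply(seq_along(markers), function(k)
      fit_mixture_1d(expr[normalize_gene_ids(markers[k]), ],
                     seed = seed + 100L + k, marker = markers[k])),
      markers),
    error = function(e) stop(stage, ": ", conditionMessage(e), call. = FALSE))
  calls <- call_receptor_status(expr, fits, threshold = thr$posterior)
  tnbc_ids <- identify_tnbc(calls)
  utils::write.csv(calls, file.path(out_dir, "receptor_calls.csv"),
                   row.names = FALSE)
  counts$receptor_calls <- nrow(calls)
  counts$tnbc <- length(tnbc_ids)

  # stage 3: subtype and refine -------------------------------------------
  stage <- "subtype"
  if (counts$tnbc == 0L)
    stop(stage, ": no TNBC samples identified", call. = FALSE)
  sub <- tryCatch(
    subtype_samples(expr[setdiff(rownames(expr), normalize_gene_ids(markers)),
                         tnbc_ids, drop = FALSE],
                    centroids, uns_threshold = thr$uns,
                    min_overlap = thr$min_overlap),
    error = function(e) stop(stage, ": ", conditionMessage(e), call. = FALSE))
  utils::write.csv(sub, file.path(out_dir, "subtypes.csv"), row.names = FALSE)
  counts$subtyped <- nrow(sub)

  # stage 4: clinical report ----------------------------------------------
  stage <- "clinical"
  report <- NULL
  if (!is.null(clinical)) {
    clin <- clinical[clinical$sample_id %in% tnbc_ids, , drop = FALSE]
    clin$subtype <- sub$call4[match(clin$sample_id, sub$sample_id)]
    report <- tryCatch(subtype_outcome_report(clin, by = "subtype",
                                              ci_method = thr$ci_method),
                       error = function(e) stop(stage, ": ",
                         conditionMessage(e), call. = FALSE))
    if (!is.null(report$pcr_table))
      utils::write.csv(report$pcr_table, file.path(out_dir, "pcr_report.csv"),
                       row.names = FALSE)
    counts$clinical <- nrow(clin)
  }

  json_report <- list(
    tnbc_ids = tnbc_ids,
    subtype_distribution = as.list(table(sub$call4)),
    pcr = if (!is.null(report$pcr_table)) report$pcr_table else NULL,
    pcr_contingency_p = if (!is.null(report$pcr_contingency))
      report$pcr_contingency$p_value else NULL)
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("tnbctype4")),
                   input_hashes = hashes, row_counts = counts,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# classed condition helper for configuration / input errors
tnbc_error <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL))
}
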