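#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 expression values
#' with unique row names (gene or probe identifiers, matched case- and
#' whitespace-insensitively throughout the package) and unique column names
#' (sample identifiers). All values must be finite.
#'
#' @param values numeric matrix, genes/probes in rows, samples in columns.
#' @param gene_ids optional character vector of row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids optional character vector of column identifiers;
#'   defaults to `colnames(values)`.
#' @param normalize_ids uppercase and strip whitespace from gene ids
#'   (default TRUE).
#' @return the validated matrix with normalized dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              normalize_ids = TRUE) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("expression matrix is empty")
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix requires gene and sample identifiers")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (normalize_ids) gene_ids <- normalize_gene_ids(gene_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers after normalization: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' @rdname expression_matrix
#' @param x character vector of identifiers.
#' @export
normalize_gene_ids <- function(x) toupper(trimws(as.character(x)))

#' Read an expression matrix
#'
#' Reads a genes-by-samples table of log2 expression values. The first
#' column holds gene or probe identifiers and the header row holds sample
#' identifiers. The `series_matrix` dialect extracts only the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` of a GEO
#' series-matrix file (tab-separated, identifiers possibly quoted); all
#' other annotation lines are ignored.
#'
#' Duplicate probe rows are preserved as distinct rows (collapse to gene
#' level is a separate step, [collapse_probes()]); row identifiers must
#' still be unique.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"csv"`, `"series_matrix"`.
#' @return a validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path, dialect = c("tsv", "csv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "series_matrix") {
    lines <- readLines(path, warn = FALSE)
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
      stop("no series-matrix table block found in ", path)
    df <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
  }
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty expression table in ", path)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v)) {
        i <- which(is.na(num))[1]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     v[i], ids[i], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m)
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()] for the `tsv`/`csv` dialects: first column
#' `gene_id`, one column per sample, UTF-8, `.` decimal separator. Values
#' are written at full double precision so a read/write round trip is
#' bitwise exact.
#'
#' @param m expression matrix.
#' @param path output file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_expression <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  m <- expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Microarray matrices often carry several probes per gene. This maps probe
#' rows to genes through a probe map and collapses multi-probe genes by one
#' of three rules: `max_variance` keeps the probe with the largest variance
#' across samples, `mean` averages probes, and `named_probe` keeps exactly
#' the probe listed in the map for each gene (the map must then be
#' one-probe-per-gene for the genes of interest).
#'
#' @param m expression matrix with probe identifiers as row names.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene allowed).
#' @param method collapse rule.
#' @return expression matrix with one row per mapped gene.
#' @export
collapse_probes <- function(m, probe_map,
                            method = c("max_variance", "mean", "named_probe")) {
  method <- match.arg(method)
  m <- expression_matrix(m)
  stopifnot(is.data.frame(probe_map),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  pm <- data.frame(probe_id = normalize_gene_ids(probe_map$probe_id),
                   gene_id = normalize_gene_ids(probe_map$gene_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$probe_id))
    stop("probe map assigns some probe to more than one gene")
  if (method == "named_probe") {
    missing <- setdiff(pm$probe_id, rownames(m))
    if (length(missing))
      stop("named probes absent from matrix: ",
           paste(missing, collapse = ", "))
  }
  pm <- pm[pm$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(pm) == 0L) stop("no probes in the map match matrix rows")
  genes <- unique(pm$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    probes <- pm$probe_id[pm$gene_id == g]
    sub <- m[probes, , drop = FALSE]
    out[g, ] <- switch(method,
      mean = colMeans(sub),
      max_variance = sub[which.max(apply(sub, 1, stats::var)), ],
      named_probe = {
        if (nrow(sub) > 1L)
          stop("named_probe lists more than one probe for gene ", g)
        sub[1, ]
      })
  }
  expression_matrix(out)
}

#' Read a centroid file
#'
#' Centroid files are TSV/CSV with header `gene_id,<subtype...>` and numeric
#' weights (standardized log2 units). Optionally row-standardizes the
#' weights on load.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param intrinsic subtype names regarded as tumor-intrinsic; defaults to
#'   the intersection of the file's subtypes with BL1/BL2/M/LAR.
#' @param standardize row-standardize weights on load (default FALSE: the
#'   file is assumed pre-standardized).
#' @return a [centroid_set()].
#' @export
read_centroids <- function(path, dialect = c("tsv", "csv"), intrinsic = NULL,
                           standardize = FALSE) {
  dialect <- match.arg(dialect)
  m <- read_expression(path, dialect)
  if (standardize) m <- t(scale(t(m)))
  centroid_set(m, intrinsic = intrinsic)
}

#' Write a centroid set
#' @param cs a [centroid_set()].
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_centroids <- function(cs, path, dialect = c("tsv", "csv")) {
  write_expression(unclass(cs$weights), path, match.arg(dialect))
}

#' Read a clinical annotation table
#'
#' Expected columns (missing ones tolerated, extra ones preserved):
#' sample_id, subtype, pcr (0/1/NA), age, grade, stage, node_positive,
#' tumor_size_mm, met_brain, met_bone, met_lung, os_time, os_event,
#' rfs_time, rfs_event, drfs_time, drfs_event, im_score.
#'
#' @param path CSV file path.
#' @return data.frame with `sample_id` as character.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table lacks 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  for (col in intersect(c("os_time", "rfs_time", "drfs_time"), names(df)))
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative survival time in ", col)
  for (col in intersect(c("os_event", "rfs_event", "drfs_event"), names(df)))
    if (!all(df[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  df
}
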