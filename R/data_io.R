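# Input/output for intensity tables, batch information and run
# configuration.  The on-disk dialect is deliberately minimal:
#   * intensity matrix: CSV/TSV, header row = feature IDs, first column =
#     sample IDs (or transposed, see `transpose`);
#   * batch info: CSV/TSV with columns sample, batch, group (empty group
#     marks a non-reference sample);
#   * run configuration: flat "key: value" / "key = value" text file.

#' Read an intensity matrix from CSV/TSV
#'
#' The first column holds sample names and the header row holds feature
#' names (set `transpose = TRUE` for tables stored features-in-rows).
#' Empty cells, `NA` and `NaN` are read as missing values; every other
#' cell must be numeric.
#'
#' @param path path to a CSV or TSV file (delimiter auto-detected).
#' @param transpose logical; if `TRUE` the file is features x samples and
#'   is transposed after reading.
#' @return Numeric matrix, samples in rows (rownames = sample IDs),
#'   features in columns (colnames = feature IDs); missing cells are `NA`.
#' @export
read_intensities <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA", "NaN"),
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stop("intensity table needs at least one data column: ", path)
  ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric cells in column(s): ", paste(names(vals)[bad], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  .check_unique(rownames(m), "sample")
  .check_unique(colnames(m), "feature")
  m
}

.check_unique <- function(ids, what) {
  if (is.null(ids)) stop("missing ", what, " names")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated ", what, " name(s): ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}

#' Read a batch-information table
#'
#' Expects columns `sample`, `batch` and optionally `group`; an empty or
#' missing group marks a non-reference sample.
#'
#' @param path path to a CSV/TSV file.
#' @return `data.frame` with character columns `sample`, `batch`, `group`
#'   (`group` is `""` for non-reference samples).
#' @export
read_batch_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = character(0), data.table = FALSE)
  names(dt) <- tolower(names(dt))
  if (!all(c("sample", "batch") %in% names(dt))) {
    stop("batch info must have columns 'sample' and 'batch': ", path)
  }
  if (!"group" %in% names(dt)) dt$group <- ""
  dt$group[is.na(dt$group)] <- ""
  .check_unique(dt$sample, "sample")
  dt[, c("sample", "batch", "group")]
}

#' Replace missing and sub-threshold intensities
#'
#' Every missing cell and every cell below `min_relevant_intensity` is set
#' to `min_relevant_intensity` (default 1000 counts), the lowest intensity
#' the method considers meaningful.  Sub-threshold values are treated
#' identically to missing values, which unifies detection-limit censoring
#' with explicit missingness and guarantees strict positivity.
#'
#' @param m numeric matrix (may contain `NA`).
#' @param min_relevant_intensity positive scalar, in counts.
#' @return Matrix with `min(m) >= min_relevant_intensity` and no `NA`.
#' @export
apply_min_intensity <- function(m, min_relevant_intensity = 1000) {
  stopifnot(is.matrix(m), is.numeric(min_relevant_intensity),
            length(min_relevant_intensity) == 1, min_relevant_intensity > 0)
  m[is.na(m) | m < min_relevant_intensity] <- min_relevant_intensity
  m
}

#' Validate an intensity matrix against its batch information
#'
#' Produces a validation report and fails hard on conditions that make
#' normalization impossible: a sample without a batch label, or no
#' reference group whose members span at least two batches.  Softer
#' issues (batches with fewer than two samples, reference groups confined
#' to a single batch, constant features, the fraction of cells that the
#' minimum-intensity rule replaces) are reported but do not error.
#'
#' @param m intensity matrix as read by [read_intensities()] (missing
#'   cells may still be `NA`).
#' @param b batch info `data.frame` (see [read_batch_info()]).
#' @param min_relevant_intensity threshold used to compute the replaced
#'   fraction; default 1000 counts.
#' @return Object of class `"mb_validation"`: a list with
#'   `samples_missing_batch`, `small_batches`, `single_batch_groups`,
#'   `constant_features`, `replaced_fraction`, `n_batches`, `groups`.
#' @export
validate_inputs <- function(m, b, min_relevant_intensity = 1000) {
  stopifnot(is.matrix(m), is.data.frame(b))
  idx <- match(rownames(m), b$sample)
  missing_batch <- rownames(m)[is.na(idx) | b$batch[idx] %in% c("", NA)]
  if (length(missing_batch)) {
    stop("sample(s) without batch label: ", paste(missing_batch, collapse = ", "))
  }
  bsub <- b[idx, , drop = FALSE]

  groups <- unique(bsub$group[bsub$group != ""])
  span <- vapply(groups, function(g) {
    length(unique(bsub$batch[bsub$group == g]))
  }, integer(1))
  single_batch_groups <- groups[span < 2]
  if (length(groups) == 0 || all(span < 2)) {
    stop("no reference group spans >= 2 batches",
         if (length(single_batch_groups))
           paste0(" (single-batch group(s): ",
                  paste(single_batch_groups, collapse = ", "), ")") else "")
  }

  batch_sizes <- table(bsub$batch)
  replaced <- m
  replaced_n <- sum(is.na(m) | m < min_relevant_intensity)
  filled <- apply_min_intensity(m, min_relevant_intensity)
  const_feat <- colnames(m)[apply(filled, 2, function(v) diff(range(v)) == 0)]

  structure(list(
    samples_missing_batch = character(0),
    small_batches = names(batch_sizes)[batch_sizes < 2],
    single_batch_groups = single_batch_groups,
    constant_features = const_feat,
    replaced_fraction = replaced_n / length(m),
    n_batches = length(batch_sizes),
    groups = groups
  ), class = "mb_validation")
}

#' @exportS3Method base::print
print.mb_validation <- function(x, ...) {
  cat("Input validation:\n")
  cat("  batches:", x$n_batches,
      " reference groups:", length(x$groups), "\n")
  cat("  replaced cell fraction:", format(x$replaced_fraction, digits = 4), "\n")
  if (length(x$small_batches))
    cat("  batches with <2 samples:", paste(x$small_batches, collapse = ", "), "\n")
  if (length(x$single_batch_groups))
    cat("  single-batch reference groups:",
        paste(x$single_batch_groups, collapse = ", "), "\n")
  if (length(x$constant_features))
    cat("  constant features:", length(x$constant_features), "\n")
  invisible(x)
}

#' Write an intensity matrix to CSV
#'
#' Values are written at full precision so that
#' `read_intensities(write_normalized(m, path))` round-trips bit-exactly.
#'
#' @param m numeric matrix with sample rownames and feature colnames.
#' @param path output path; its directory must exist.
#' @export
write_normalized <- function(m, path) {
  stopifnot(is.matrix(m))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- vapply(seq_len(ncol(m)), function(j) {
    out <- trimws(formatC(m[, j], digits = 17, format = "g"))
    out[is.na(m[, j])] <- ""
    out
  }, character(nrow(m)))
  if (nrow(m) == 1) chr <- matrix(chr, nrow = 1)
  colnames(chr) <- colnames(m)
  dt <- data.table::data.table(sample = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(chr))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

# -- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults: the minimum relevant
#' intensity (1000 counts), the PCA variance ratio sizing the bottleneck
#' (0.9), the randomized grid size (50), log-uniform sampling ranges for
#' the loss weights (1e-3..10) and learning rates (1e-4..1e-2), epochs,
#' and the master seed.
#'
#' @param ... named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    data_path = NULL,
    info_path = NULL,
    out_dir = ".",
    transpose = FALSE,
    min_relevant_intensity = 1000,
    variance_ratio = 0.9,
    latent_dim = NA,            # NA = use variance_ratio rule
    grid_size = 50,
    lambda_g_range = c(1e-3, 10),
    lambda_d_range = c(1e-3, 10),
    lambda_v_range = c(1e-3, 10),
    lr_range = c(1e-4, 1e-2),
    epochs = 100,
    batch_size = 32,
    patience = 5,
    window = 20,
    collapse_ratio = 1e-3,
    reconstruction = "mse",
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  .validate_config(cfg)
}

.validate_config <- function(cfg) {
  stopifnot(cfg$variance_ratio > 0, cfg$variance_ratio <= 1,
            cfg$min_relevant_intensity > 0, cfg$grid_size >= 1,
            cfg$epochs >= 1, cfg$batch_size >= 2)
  cfg
}

#' Read a run configuration file
#'
#' A flat text file of `key: value` (or `key = value`) lines; `#` starts a
#' comment.  Two-element ranges are comma-separated (`lambda_d_range:
#' 0.001, 10`).  Unset keys fall back to [default_config()].
#'
#' @param path path to the configuration file.
#' @return Named list as from [default_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad)) stop("cannot parse config line(s): ", paste(bad, collapse = "; "))
  vals <- lapply(kv, function(x) .parse_config_value(trimws(x[3])))
  names(vals) <- vapply(kv, `[`, character(1), 2)
  do.call(default_config, vals)
}

.parse_config_value <- function(v) {
  if (grepl(",", v, fixed = TRUE)) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    return(parts)
  }
  if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
  if (tolower(v) %in% c("na", "null")) return(NA)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}
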