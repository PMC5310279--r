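# Input handling: expression matrices, survival tables and gene-set
# collections, assembled into the canonical survival_dataset that every
# selection strategy consumes. Internal layout is samples x features (rows =
# subjects), matching the regression notation; expression files keep the
# features-in-rows convention usual for microarray exports.

#' Construct a survival dataset
#'
#' The canonical container of the package: a numeric design matrix `X`
#' (samples in rows, features in columns), aligned positive follow-up times
#' and 0/1 event indicators, with unique feature and sample identifiers.
#' Validation requires at least two observed events, below which Cox fitting
#' is degenerate.
#'
#' @param X Numeric matrix, n samples x p features, no missing values.
#' @param time Positive numeric vector of length n (one time unit
#'   throughout, e.g. months).
#' @param event Integer/numeric vector of length n with values in `{0, 1}`
#'   (1 = event observed, 0 = right-censored).
#' @param feature_ids,sample_ids Unique label vectors of length p and n;
#'   defaults taken from `dimnames(X)` or generated.
#' @return An object of class `survival_dataset` with fields `X`, `time`,
#'   `event`, `feature_ids`, `sample_ids`, `n`, `p`.
#' @export
survival_dataset <- function(X, time, event, feature_ids = colnames(X),
                             sample_ids = rownames(X)) {
  X <- as.matrix(X)
  if (is.null(feature_ids)) feature_ids <- sprintf("F%05d", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(X)))
  if (!is.numeric(X) || anyNA(X)) stop("X must be numeric with no missing values")
  if (length(time) != nrow(X) || length(event) != nrow(X)) {
    stop("time/event length must equal the number of samples (rows of X)")
  }
  if (any(!is.finite(time)) || any(time <= 0)) stop("all follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (sum(event == 1) < 2) stop("need at least 2 samples with an observed event")
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(
    list(X = X, time = as.numeric(time), event = as.integer(event),
         feature_ids = as.character(feature_ids),
         sample_ids = as.character(sample_ids),
         n = nrow(X), p = ncol(X)),
    class = "survival_dataset"
  )
}

#' @rdname survival_dataset
#' @param x Object to test.
#' @export
is_survival_dataset <- function(x) inherits(x, "survival_dataset")

#' @export
print.survival_dataset <- function(x, ...) {
  cat("survival_dataset:", x$n, "samples x", x$p, "features;",
      sum(x$event), "events (", round(100 * mean(x$event == 0), 1),
      "% censored )\n")
  invisible(x)
}

# Map feature ids or indices onto column indices, with validation.
resolve_features <- function(ds, features) {
  if (length(features) == 0L) return(integer(0))
  if (is.character(features)) {
    idx <- match(features, ds$feature_ids)
    if (anyNA(idx)) stop("unknown feature id(s): ",
                         paste(features[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(features)
  if (any(idx < 1L | idx > ds$p)) stop("feature index out of range 1..", ds$p)
  idx
}

#' Subset a survival dataset
#'
#' `subset_features()` keeps the given feature columns (by index or id, in
#' ascending original order); `subset_samples()` keeps the given samples in
#' the requested order. Survival fields travel with the samples.
#'
#' @param ds A [survival_dataset].
#' @param features,samples Indices or ids to retain.
#' @return A [survival_dataset].
#' @export
subset_features <- function(ds, features) {
  idx <- sort(resolve_features(ds, features))
  survival_dataset(ds$X[, idx, drop = FALSE], ds$time, ds$event,
                   feature_ids = ds$feature_ids[idx],
                   sample_ids = ds$sample_ids)
}

#' @rdname subset_features
#' @export
subset_samples <- function(ds, samples) {
  idx <- if (is.character(samples)) match(samples, ds$sample_ids) else as.integer(samples)
  if (anyNA(idx) || any(idx < 1L | idx > ds$n)) stop("unknown sample selection")
  survival_dataset(ds$X[idx, , drop = FALSE], ds$time[idx], ds$event[idx],
                   feature_ids = ds$feature_ids,
                   sample_ids = ds$sample_ids[idx])
}

#' Read an expression matrix from delimited text
#'
#' Expects one header row and one leading label column; the delimiter (tab or
#' comma) is inferred from the header. The declared orientation is normalized
#' so the result is always features x samples. Any missing or non-numeric
#' cell is an error naming its location — post-normalization expression
#' matrices are expected to be complete, and no imputation is attempted.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"features_in_rows"` (default; rows are features,
#'   columns are samples) or `"samples_in_rows"` for the transpose.
#' @return An object of class `expression_matrix` with fields `values`
#'   (features x samples), `feature_ids`, `sample_ids`.
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only expression file: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[[1L]])) {
    stop("ragged expression file: line ", which(widths != widths[[1L]])[1L],
         " has ", widths[widths != widths[[1L]]][1L], " fields, expected ",
         widths[[1L]])
  }
  header <- cells[[1L]]
  col_ids <- header[-1L]
  row_ids <- vapply(cells[-1L], `[[`, "", 1L)
  if (anyDuplicated(col_ids)) {
    stop("duplicate column label(s): ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row label(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  raw <- t(vapply(cells[-1L], function(r) r[-1L], character(length(col_ids))))
  if (length(col_ids) == 1L) raw <- matrix(raw, ncol = 1L)
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing cell '%s' at row '%s', column '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]], row_ids[bad[1L, 1L]],
                 col_ids[bad[1L, 2L]]))
  }
  if (orientation == "samples_in_rows") {
    vals <- t(vals)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  structure(list(values = vals, feature_ids = row_ids, sample_ids = col_ids),
            class = "expression_matrix")
}

#' Write an expression matrix to tab-separated text
#'
#' Features in rows, samples in columns, full-precision values, so a
#' [read_expression()] round trip reproduces labels exactly and values to
#' float-formatting accuracy.
#'
#' @param expr An `expression_matrix` (or a [survival_dataset], whose `X` is
#'   transposed to the features-in-rows file convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  if (is_survival_dataset(expr)) {
    expr <- structure(list(values = t(expr$X), feature_ids = expr$feature_ids,
                           sample_ids = expr$sample_ids),
                      class = "expression_matrix")
  }
  stopifnot(inherits(expr, "expression_matrix"))
  header <- paste(c("feature_id", expr$sample_ids), collapse = "\t")
  body <- vapply(seq_along(expr$feature_ids), function(i) {
    paste(c(expr$feature_ids[i],
            format(expr$values[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a survival table
#'
#' CSV with required columns `sample_id`, `time`, `event`. Times must be
#' positive; events must be 0/1; sample ids must be unique.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `survival_table`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("survival table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  if (!is.numeric(tab$time) || anyNA(tab$time) || any(tab$time <= 0)) {
    stop("survival times must be positive numbers")
  }
  if (!all(tab$event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  tab$sample_id <- as.character(tab$sample_id)
  class(tab) <- c("survival_table", "data.frame")
  tab
}

#' Write a survival table as CSV
#'
#' @param ds A [survival_dataset] or `survival_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(ds, path) {
  tab <- if (is_survival_dataset(ds)) {
    data.frame(sample_id = ds$sample_ids, time = ds$time, event = ds$event)
  } else {
    as.data.frame(ds)[, c("sample_id", "time", "event")]
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align expression and survival records into a dataset
#'
#' Retains the intersection of the two sample-id sets, ordered as in the
#' survival table, and transposes the expression values into the samples x
#' features layout. Ids present on only one side are dropped; the drop report
#' is attached as `attr(, "dropped")`.
#'
#' @param expr An `expression_matrix` from [read_expression()].
#' @param surv A `survival_table` from [read_survival()], or any data frame
#'   with columns `sample_id`, `time`, `event`.
#' @return A [survival_dataset].
#' @export
assemble_dataset <- function(expr, surv) {
  stopifnot(inherits(expr, "expression_matrix"))
  surv <- as.data.frame(surv)
  keep <- surv$sample_id[surv$sample_id %in% expr$sample_ids]
  if (length(keep) == 0L) stop("expression and survival tables share no sample ids")
  sub <- surv[match(keep, surv$sample_id), ]
  if (sum(sub$event == 1) < 2) {
    stop("fewer than 2 events among the shared samples; Cox fitting is degenerate")
  }
  X <- t(expr$values[, match(keep, expr$sample_ids), drop = FALSE])
  ds <- survival_dataset(X, sub$time, sub$event,
                         feature_ids = expr$feature_ids, sample_ids = keep)
  attr(ds, "dropped") <- list(
    expression_only = setdiff(expr$sample_ids, surv$sample_id),
    survival_only = setdiff(surv$sample_id, expr$sample_ids)
  )
  ds
}

#' Filter features by interquartile range
#'
#' Near-constant features carry no usable signal for regression and inflate
#' the multiplicity burden, so the standard pre-filter keeps only the most
#' variable fraction. Per feature, the IQR of its n values is computed with
#' the linear-interpolation quantile convention (R's type 7); the
#' `ceiling(keep_fraction * p)` features with the largest IQR are retained,
#' ties broken in favour of the earlier original position. Alternatively an
#' absolute cutoff `min_iqr` keeps every feature whose IQR reaches it.
#' Survival fields and retained values are untouched, so the filter is
#' idempotent at a fixed setting.
#'
#' @param ds A [survival_dataset].
#' @param keep_fraction Fraction of features to keep, in `(0, 1]`. Default
#'   0.2, a typical microarray setting.
#' @param min_iqr Optional absolute IQR cutoff; overrides `keep_fraction`.
#' @return The filtered [survival_dataset], with the per-feature IQRs of the
#'   retained features in `attr(, "iqr")`.
#' @export
iqr_filter <- function(ds, keep_fraction = 0.2, min_iqr = NULL) {
  stopifnot(is_survival_dataset(ds))
  iqrs <- apply(ds$X, 2L, stats::IQR, type = 7)
  if (!is.null(min_iqr)) {
    keep <- which(iqrs >= min_iqr)
    if (length(keep) == 0L) stop("no feature reaches min_iqr = ", min_iqr)
  } else {
    if (!(keep_fraction > 0 && keep_fraction <= 1)) {
      stop("keep_fraction must lie in (0, 1]")
    }
    m <- ceiling(keep_fraction * ds$p)
    keep <- sort(order(iqrs, decreasing = TRUE)[seq_len(m)])
  }
  out <- subset_features(ds, keep)
  attr(out, "iqr") <- iqrs[keep]
  out
}

#' Read a gene-set collection in GMT format
#'
#' One set per line, tab-separated: set name, description, then member gene
#' ids. Duplicate members within a line are dropped; a duplicate set name or
#' a line with fewer than three fields is an error.
#'
#' @param path Path to a `.gmt` file.
#' @return An object of class `gene_set_collection`: a named list of
#'   `list(description=, genes=)` entries.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) {
    list(description = f[[2L]], genes = unique(f[-(1:2)]))
  })
  names(sets) <- names_
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
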