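## Expression / clinical table IO and cohort assembly.
##
## Canonical orientation throughout the package: features x samples, mirroring
## the array-platform matrices the inputs emulate.

#' Construct and validate an expression matrix
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids character vector of unique feature (miRNA) identifiers.
#' @param sample_ids character vector of unique sample identifiers.
#' @return A numeric matrix with feature row names and sample column names.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature_ids and sample_ids are required")
  }
  if (nrow(values) != length(feature_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions do not match identifier lists")
  }
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup)) stop("duplicate feature identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at feature '", feature_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

#' Read an expression matrix from tab-delimited text
#'
#' Reads a TSV whose first column (or first row, for `samples_in_rows`) holds
#' identifiers, and returns the matrix in the canonical features-x-samples
#' orientation.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param impute_missing if `TRUE`, missing cells are imputed by the per-feature
#'   mean; the default refuses missing values.
#' @return An expression matrix (features x samples).
#' @export
read_expression_tsv <- function(path,
                                orientation = c("features_in_rows", "samples_in_rows"),
                                impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expected an identifier column plus at least one data column")
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells == "" | toupper(cells) == "NA"),
               arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop("non-numeric cell '", cells[bad[1, 1], bad[1, 2]], "' at row '",
         row_ids[bad[1, 1]], "', column '", col_ids[bad[1, 2]], "'")
  }
  m <- num
  dimnames(m) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyNA(m)) {
    if (!impute_missing) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("missing expression value at feature '", rownames(m)[bad[1]],
           "', sample '", colnames(m)[bad[2]],
           "' (set impute_missing = TRUE to mean-impute)")
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      mu <- mean(m[i, ], na.rm = TRUE)
      if (!is.finite(mu)) stop("feature '", rownames(m)[i], "' is entirely missing")
      m[i, is.na(m[i, ])] <- mu
    }
  }
  expression_matrix(m)
}

#' Write an expression matrix as tab-delimited text
#'
#' @param expr expression matrix (features x samples).
#' @param path output path.
#' @param id_column header name of the identifier column.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expr, path, id_column = "miRNA") {
  atomic_write(path, function(tmp) {
    df <- data.frame(rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_column
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Default clinical column-name map
#' @return Named list mapping logical fields to TSV column names.
#' @export
clinical_column_map <- function(sample_id = "sample_id",
                                days_to_death = "days_to_death",
                                received_therapy = "received_therapy",
                                vital_status = "vital_status") {
  list(sample_id = sample_id, days_to_death = days_to_death,
       received_therapy = received_therapy, vital_status = vital_status)
}

#' Read a clinical table from tab-delimited text
#'
#' Returns one record per input row. Absent days-to-death values (empty or NA
#' cells) are parsed as missing, never as zero; duplicate sample ids are kept
#' and resolved later by [apply_cohort_filters()].
#'
#' @param path path to a TSV with a header row.
#' @param col_map column-name map from [clinical_column_map()].
#' @return A data.frame with columns `sample_id`, `days_to_death` (integer,
#'   `NA` when absent), `received_therapy` (logical), `vital_status`
#'   (`"dead"`, `"alive"` or `"unknown"`).
#' @export
read_clinical_tsv <- function(path, col_map = clinical_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "",
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(unlist(col_map), colnames(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s) ", paste(missing_cols, collapse = ", "),
         "; available columns: ", paste(colnames(df), collapse = ", "))
  }
  days <- suppressWarnings(as.integer(df[[col_map$days_to_death]]))
  bad <- !is.na(df[[col_map$days_to_death]]) & is.na(days)
  if (any(bad)) stop("non-integer days_to_death value '",
                     df[[col_map$days_to_death]][which(bad)[1]], "'")
  if (any(days < 0, na.rm = TRUE)) stop("negative days_to_death")
  therapy <- tolower(df[[col_map$received_therapy]]) %in% c("true", "t", "1", "yes", "y")
  vs <- tolower(df[[col_map$vital_status]])
  vs[!vs %in% c("dead", "alive")] <- "unknown"
  out <- data.frame(sample_id = df[[col_map$sample_id]],
                    days_to_death = days,
                    received_therapy = therapy,
                    vital_status = vs,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$sample_id) | is.na(out$sample_id))) stop("empty sample_id")
  out
}

#' Apply the cohort inclusion filters
#'
#' Retains clinical records that (i) received therapy, (ii) have survival
#' information (days to death), (iii) survived at least `min_survival_days`,
#' and (iv) are unique after merging duplicate entries. Each removal is
#' attributed to the first failing criterion, evaluated in that order.
#'
#' @param records clinical data.frame from [read_clinical_tsv()].
#' @param min_survival_days minimum survival period in days (default 30).
#' @param duplicate_policy `"error"` (default) fails on duplicate sample ids
#'   with conflicting survival; `"keep_max"` merges them keeping the maximum.
#' @return A list with `records` (the retained data.frame) and `report`, a
#'   `filter_report` counting input, per-criterion removals and retained rows.
#' @export
apply_cohort_filters <- function(records, min_survival_days = 30,
                                 duplicate_policy = c("error", "keep_max")) {
  duplicate_policy <- match.arg(duplicate_policy)
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  n_in <- nrow(records)
  removed <- c(no_therapy = 0L, no_survival_info = 0L,
               short_survival = 0L, duplicate_merged = 0L)

  keep <- records$received_therapy
  removed["no_therapy"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- !is.na(records$days_to_death)
  removed["no_survival_info"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  keep <- records$days_to_death >= min_survival_days
  removed["short_survival"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  if (nrow(records)) {
    dup_ids <- unique(records$sample_id[duplicated(records$sample_id)])
    if (length(dup_ids)) {
      for (id in dup_ids) {
        days <- unique(records$days_to_death[records$sample_id == id])
        if (length(days) > 1 && duplicate_policy == "error") {
          stop("duplicate sample id '", id, "' with conflicting days_to_death (",
               paste(sort(days), collapse = ", "),
               "); use duplicate_policy = \"keep_max\" to merge")
        }
      }
      first <- !duplicated(records$sample_id)
      merged <- stats::aggregate(days_to_death ~ sample_id, records, max)
      removed["duplicate_merged"] <- sum(!first)
      records <- records[first, , drop = FALSE]
      records$days_to_death <-
        merged$days_to_death[match(records$sample_id, merged$sample_id)]
    }
  }

  report <- structure(list(input = n_in, removed = as.list(removed),
                           retained = nrow(records)),
                      class = "filter_report")
  list(records = records, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Cohort filter report:", x$input, "records in,", x$retained, "retained\n")
  for (nm in names(x$removed)) cat("  removed (", nm, "): ", x$removed[[nm]], "\n", sep = "")
  invisible(x)
}

#' Assemble an aligned modelling cohort
#'
#' Restricts the expression matrix and filtered clinical records to their
#' common samples (sorted sample id, so the result is independent of input
#' order) and converts survival to years.
#'
#' @param expr expression matrix, features x samples.
#' @param records filtered clinical data.frame (unique sample ids, all with
#'   `days_to_death`).
#' @param days_per_year day-to-year conversion constant (default 365.25).
#' @return A `cohort`: list with `expression` (features x samples) and
#'   `survival_years` (named numeric, aligned to the sample columns).
#' @export
assemble_cohort <- function(expr, records, days_per_year = 365.25) {
  stopifnot(is.matrix(expr), is.data.frame(records))
  if (anyDuplicated(records$sample_id)) stop("records must have unique sample ids")
  if (anyNA(records$days_to_death)) stop("records must all carry days_to_death")
  common <- sort(intersect(colnames(expr), records$sample_id))
  if (!length(common)) stop("no overlap between expression and clinical sample ids")
  dropped <- setdiff(records$sample_id, colnames(expr))
  if (length(dropped)) {
    message(length(dropped), " clinical record(s) without expression data excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  days <- records$days_to_death[match(common, records$sample_id)]
  surv <- days / days_per_year
  if (any(surv <= 0)) stop("non-positive survival time after filtering")
  names(surv) <- common
  cohort(expr[, common, drop = FALSE], surv)
}

#' Construct a cohort object
#'
#' @param expression expression matrix, features x samples.
#' @param survival_years positive numeric vector aligned to the sample columns.
#' @return An object of class `cohort`.
#' @export
cohort <- function(expression, survival_years) {
  stopifnot(is.matrix(expression), is.numeric(survival_years))
  if (length(survival_years) != ncol(expression)) {
    stop("survival_years length must equal the number of samples")
  }
  if (any(!is.finite(survival_years)) || any(survival_years <= 0)) {
    stop("survival_years must be finite and positive")
  }
  if (is.null(names(survival_years))) names(survival_years) <- colnames(expression)
  if (!identical(names(survival_years), colnames(expression))) {
    stop("survival_years names must match expression sample ids")
  }
  structure(list(expression = expression, survival_years = survival_years),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", nrow(x$expression), " features x ", ncol(x$expression),
      " samples; survival ", round(min(x$survival_years), 2), "-",
      round(max(x$survival_years), 2), " years\n", sep = "")
  invisible(x)
}

#' Write a cohort back to paired TSV files
#'
#' @param x a `cohort`.
#' @param expr_path path for the expression TSV.
#' @param clinical_path path for the survival TSV
#'   (`sample_id`, `survival_years`).
#' @return Invisibly, the two paths.
#' @export
write_cohort_tsv <- function(x, expr_path, clinical_path) {
  stopifnot(inherits(x, "cohort"))
  write_expression_tsv(x$expression, expr_path)
  atomic_write(clinical_path, function(tmp) {
    utils::write.table(
      data.frame(sample_id = names(x$survival_years),
                 survival_years = unname(x$survival_years)),
      tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(c(expr_path, clinical_path))
}
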