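#' Read a cell table
#'
#' Reads a per-cell CSV (one row per segmented cell) with columns
#' `cell_id`, `region_id`, `x_um`, `y_um` and one 0/1 positivity column per
#' panel marker. Marker positivity is consumed as already-thresholded
#' binary calls; any mean-intensity columns present are ignored. Row order
#' is preserved.
#'
#' @param path CSV file path.
#' @param markers Ordered marker names whose 0/1 columns must be present.
#' @return Data frame with logical marker columns; attribute `markers`
#'   records the marker order.
#' @export
read_cell_table <- function(path, markers = PANEL_MARKERS) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("cell_id", "region_id", "x_um", "y_um", markers)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cell table schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "))
  }
  df$cell_id <- as.character(df$cell_id)
  df$region_id <- as.character(df$region_id)
  if (anyDuplicated(df$cell_id)) {
    stop("cell table contains duplicate cell_id: ",
         df$cell_id[duplicated(df$cell_id)][1])
  }
  if (any(df$x_um < 0) || any(df$y_um < 0)) {
    stop("cell coordinates must be non-negative microns")
  }
  for (m in markers) {
    v <- df[[m]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad)) {
      stop("cell table parse error: non-0/1 positivity value '",
           v[bad[1]], "' for marker '", m, "' in row ", bad[1])
    }
    df[[m]] <- as.logical(v)
  }
  attr(df, "markers") <- markers
  df
}

#' Write a cell table
#'
#' Writes positivity columns back as 0/1 with a schema-version comment line;
#' round-trips bit-exactly through [read_cell_table()] for integers and to
#' full double precision for coordinates.
#'
#' @param cells Cell table data frame.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  markers <- attr(cells, "markers") %||% intersect(PANEL_MARKERS, names(cells))
  for (m in markers) out[[m]] <- as.integer(out[[m]])
  .write_csv_schema(out, path)
  invisible(path)
}

#' Read region metadata
#'
#' Region-level CSV with columns `region_id`, `patient_id`, `cohort`,
#' `site`, `area_mm2`. Cohort and site tokens are validated against the
#' package enumerations; duplicate regions and non-positive areas are
#' rejected.
#'
#' @param path CSV file path.
#' @return Data frame keyed by `region_id`.
#' @export
read_region_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("region_id", "patient_id", "cohort", "site", "area_mm2")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("region metadata schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "))
  }
  df$region_id <- as.character(df$region_id)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region_id: ", df$region_id[duplicated(df$region_id)][1])
  }
  bad <- setdiff(unique(df$cohort), COHORTS)
  if (length(bad)) stop("unknown cohort token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$site), SITES)
  if (length(bad)) stop("unknown site token(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$area_mm2)) || any(df$area_mm2 <= 0)) {
    stop("area_mm2 must be positive for every region")
  }
  df
}

#' Read a patient table
#'
#' Patient-level CSV with `patient_id`, `cohort` and `dfs_months`
#' (disease-free survival, months; may be empty for the treatment-naive
#' cohort).
#'
#' @param path CSV file path.
#' @return Data frame keyed by `patient_id`.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("patient_id", "cohort")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("patient table schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id: ", df$patient_id[duplicated(df$patient_id)][1])
  }
  bad <- setdiff(unique(df$cohort), COHORTS)
  if (length(bad)) stop("unknown cohort token(s): ", paste(bad, collapse = ", "))
  if (!"dfs_months" %in% names(df)) df$dfs_months <- NA_real_
  if (any(!is.na(df$dfs_months) & df$dfs_months <= 0)) {
    stop("dfs_months must be positive when present")
  }
  df
}

#' Write a generic table with the package schema-version stamp
#' @noRd
.write_csv_schema <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema_version=", SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' @rdname write_cell_table
#' @param regions Region metadata data frame.
#' @export
write_region_metadata <- function(regions, path) {
  .write_csv_schema(regions, path)
  invisible(path)
}

#' @rdname write_cell_table
#' @param patients Patient table data frame.
#' @export
write_patient_table <- function(patients, path) {
  .write_csv_schema(patients, path)
  invisible(path)
}

#' Cross-validate the three input tables
#'
#' Collects referential-integrity findings without raising: the caller
#' decides what severity aborts. Checks (a) cells referencing unknown
#' regions (error), (b) regions with zero cells (warning), (c) treated
#' patients lacking DFS when the DFS task is requested (error), and
#' (d) patients spanning two cohorts (error).
#'
#' @param cells Cell table.
#' @param regions Region metadata.
#' @param patients Patient table.
#' @param require_dfs Is the DFS task requested?
#' @return A `validation_report` data frame with columns `severity`,
#'   `code`, `message`; zero rows when the dataset is consistent.
#' @export
validate_dataset <- function(cells, regions, patients, require_dfs = FALSE) {
  entries <- list()
  add <- function(severity, code, message) {
    entries[[length(entries) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  }

  unknown <- setdiff(unique(cells$region_id), regions$region_id)
  for (r in unknown) {
    add("error", "unknown_region",
        sprintf("%d cell(s) reference unknown region '%s'",
                sum(cells$region_id == r), r))
  }

  empty <- setdiff(regions$region_id, unique(cells$region_id))
  for (r in empty) {
    add("warning", "empty_region", sprintf("region '%s' has no cells", r))
  }

  if (require_dfs) {
    trt <- patients[patients$cohort == "aCD40", , drop = FALSE]
    for (p in trt$patient_id[is.na(trt$dfs_months)]) {
      add("error", "missing_dfs",
          sprintf("aCD40 patient '%s' lacks dfs_months", p))
    }
  }

  pc <- unique(regions[, c("patient_id", "cohort")])
  multi <- names(which(table(pc$patient_id) > 1))
  for (p in multi) {
    add("error", "cohort_conflict",
        sprintf("patient '%s' spans multiple cohorts in region metadata", p))
  }
  pm <- merge(pc[!pc$patient_id %in% multi, ], patients,
              by = "patient_id", suffixes = c(".region", ".patient"))
  mism <- pm$patient_id[pm$cohort.region != pm$cohort.patient]
  for (p in mism) {
    add("error", "cohort_conflict",
        sprintf("patient '%s' cohort differs between region and patient tables", p))
  }
  unknown_pat <- setdiff(unique(regions$patient_id), patients$patient_id)
  for (p in unknown_pat) {
    add("error", "unknown_patient",
        sprintf("region metadata references unknown patient '%s'", p))
  }

  rep <- if (length(entries)) do.call(rbind, entries) else
    data.frame(severity = character(), code = character(),
               message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Dataset validation: clean (no findings)\n")
  } else {
    cat("Dataset validation:", sum(x$severity == "error"), "error(s),",
        sum(x$severity == "warning"), "warning(s)\n")
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s\n", x$severity[i], x$message[i]))
    }
  }
  invisible(x)
}

#' Write / read a feature matrix
#'
#' The CSV carries a two-row header: the first header row gives the feature
#' family (`density`, `barcode`, `interaction`) of each column, the second
#' the feature key; the first column holds region ids.
#'
#' @param fm Feature matrix as returned by [assemble_feature_matrix()].
#' @param path Output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  fam <- sub(":.*$", "", colnames(fm))
  key <- sub("^[^:]*:", "", colnames(fm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema_version=", SCHEMA_VERSION), con)
  q <- function(v) {
    needs <- grepl('[",\n]', v)
    v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
    v
  }
  writeLines(paste(c("family", q(fam)), collapse = ","), con)
  writeLines(paste(c("region_id", q(key)), collapse = ","), con)
  vals <- apply(fm, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = ","))
  writeLines(paste(q(rownames(fm)), vals, sep = ","), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- utils::read.csv(text = lines[1:2], header = FALSE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  fam <- as.character(hdr[1, -1])
  key <- as.character(hdr[2, -1])
  body <- utils::read.csv(text = lines[-(1:2)], header = FALSE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(body[, -1, drop = FALSE])
  dimnames(m) <- list(as.character(body[[1]]), paste0(fam, ":", key))
  m
}
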