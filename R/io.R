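#' Read an exposure table
#'
#' Reads a delimited text file with one row per laser exposure and
#' validates it.  Required columns: `subject_id`, `eye`, `site`, `dose`,
#' `dose_unit`, `outcome`, `session_id`.  Unknown columns are preserved but
#' ignored by the analysis.  Validation failures are reported with the
#' offending row numbers.
#'
#' @param path path to a comma-delimited file with a header row.
#' @return A tibble of validated exposure records.
#' @export
read_exposure_table <- function(path) {
  df <- read_table_checked(path)
  required <- c("subject_id", "eye", "site", "dose", "dose_unit",
                "outcome", "session_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  validate_rows(path, !is.finite(df$dose) | df$dose <= 0,
                "dose must be finite and positive")
  validate_rows(path, !(df$outcome %in% c(0, 1)),
                "outcome must be 0 or 1")
  units <- unique(df$dose_unit)
  if (length(units) > 1L) {
    abort(paste0(path, ": mixed dose units in one file: ",
                 paste(units, collapse = ", ")))
  }
  df
}

#' Read a knife-edge scan table
#'
#' Two-column delimited text: blade position (`position_um`) and
#' transmitted `signal`, header row required.
#'
#' @param path path to a comma-delimited file.
#' @return A tibble with `position_um` and `signal`.
#' @export
read_scan <- function(path) {
  df <- read_table_checked(path)
  required <- c("position_um", "signal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) < 6L) abort(paste0(path, ": scan needs at least 6 rows."))
  d <- diff(df$position_um)
  if (!(all(d > 0) || all(d < 0))) {
    abort(paste0(path, ": blade positions must be strictly monotone."))
  }
  df
}

#' Read a lesion depth table
#'
#' Columns: `site`, `lesion_depth_um`, `corneal_thickness_um`,
#' `dose_jcm2`, and optionally `modality`.
#'
#' @param path path to a comma-delimited file.
#' @return A validated tibble.
#' @export
read_depth_table <- function(path) {
  df <- read_table_checked(path)
  required <- c("site", "lesion_depth_um", "corneal_thickness_um",
                "dose_jcm2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  validate_rows(path, !is.finite(df$lesion_depth_um) | df$lesion_depth_um <= 0,
                "lesion_depth_um must be positive")
  validate_rows(path, df$corneal_thickness_um < df$lesion_depth_um,
                "corneal_thickness_um must be >= lesion_depth_um")
  validate_rows(path, !is.finite(df$dose_jcm2) | df$dose_jcm2 <= 0,
                "dose_jcm2 must be positive")
  df
}

#' Read an exposure-session table
#'
#' Columns: `session_id`, `d_1e2_um`, and optionally `d_1e2_sd_um` (the
#' session's beam-diameter SD, used as its uncertainty).
#'
#' @param path path to a comma-delimited file.
#' @return A validated tibble.
#' @export
read_session_table <- function(path) {
  df <- read_table_checked(path)
  required <- c("session_id", "d_1e2_um")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  validate_rows(path, !is.finite(df$d_1e2_um) | df$d_1e2_um <= 0,
                "d_1e2_um must be positive")
  df
}

read_table_checked <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) {
    abort(paste0(path, ": file contains a header but no data rows."))
  }
  df
}

validate_rows <- function(path, bad, message) {
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    rows <- which(bad)
    shown <- paste(head(rows, 10L), collapse = ", ")
    if (length(rows) > 10L) shown <- paste0(shown, ", ...")
    abort(paste0(path, ": ", message, " (rows ", shown, ")"))
  }
  invisible(TRUE)
}

#' Write and re-read a machine-readable analysis report
#'
#' The machine-readable form is a flat `key = value` text file with one
#' entry per line and numbers written to full precision, so a report
#' round-trips losslessly.  Keys are dot-separated paths into the report's
#' blocks.
#'
#' @param report an `ldt_report` from [run_pipeline()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ldt_report"))
  kv <- flatten_report(report)
  writeLines(paste0(names(kv), " = ", kv), path)
  invisible(path)
}

#' @rdname write_report
#' @return For `read_report()`: a named list; values that parse as numbers
#'   are numeric.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexpr(" = ", lines, fixed = TRUE),
                  invert = TRUE)
  keys <- vapply(m, `[[`, "", 1L)
  vals <- vapply(m, `[[`, "", 2L)
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out[!is.na(num)] <- as.list(num[!is.na(num)])
  names(out) <- keys
  out
}

flatten_report <- function(report) {
  fmt <- function(v) {
    if (is.numeric(v)) vapply(v, format, "", digits = 17) else as.character(v)
  }
  out <- character(0)
  add <- function(key, v) {
    out[[key]] <<- fmt(v)
  }
  walk_block <- function(prefix, block) {
    if (is.data.frame(block)) {
      for (i in seq_len(nrow(block))) {
        row_key <- if ("convention" %in% names(block)) {
          block$convention[i]
        } else {
          as.character(i)
        }
        for (col in setdiff(names(block), "convention")) {
          add(paste(prefix, row_key, col, sep = "."), block[[col]][i])
        }
      }
    } else if (is.list(block)) {
      for (nm in names(block)) {
        walk_block(paste(prefix, nm, sep = "."), block[[nm]])
      }
    } else if (!is.null(block)) {
      add(prefix, block)
    }
  }
  for (nm in names(report)) walk_block(nm, report[[nm]])
  unlist(out)
}
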