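#' Read and validate a load-test recording
#'
#' Reads a machine CSV (comma separator, "." decimal, mandatory header
#' with columns `time_ms`, `load_N`, `displacement_mm`; a `col_map` can
#' rename other exports onto these). Validation: times strictly
#' increasing, loads non-negative, displacements non-decreasing within
#' the machine displacement accuracy (jitter at the stated accuracy must
#' not hard-fail). Each corruption class errors with a message naming the
#' offending row.
#'
#' @param path CSV file path.
#' @param machine A [machine_spec()]; its `disp_accuracy_mm` sets the
#'   monotonicity tolerance.
#' @param nodule_id Identifier attached to the recording.
#' @param col_map Named character vector mapping required names to the
#'   file's column names, e.g. `c(time_ms = "Time", load_N = "Force",
#'   displacement_mm = "Ext")`.
#' @return A tibble of class `crush_recording`.
#' @export
read_load_test <- function(path, machine = machine_spec(),
                           nodule_id = sub("\\.csv$", "", basename(path)),
                           col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("read_load_test: no such file: ", path),
          class = "crushcurve_io_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) abort(paste0("read_load_test: cannot parse ", path,
                                     ": ", conditionMessage(e)),
                              class = "crushcurve_io_error")
  )
  if (nrow(df) == 0) {
    abort(paste0("read_load_test: empty file: ", path),
          class = "crushcurve_io_error")
  }
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(df)) names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  required <- c("time_ms", "load_N", "displacement_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("read_load_test: missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crushcurve_io_error")
  }
  df <- df[required]
  for (nm in required) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (any(is.na(df[[nm]]))) bad <- union(bad, which(is.na(df[[nm]])))
    if (length(bad)) {
      abort(sprintf("read_load_test: non-numeric value in column '%s' at row %d",
                    nm, bad[1]), class = "crushcurve_io_error")
    }
    df[[nm]] <- v
  }
  dt <- diff(df$time_ms)
  if (any(dt <= 0)) {
    abort(sprintf("read_load_test: time not strictly increasing at row %d",
                  which(dt <= 0)[1] + 1L), class = "crushcurve_io_error")
  }
  if (any(df$load_N < 0)) {
    abort(sprintf("read_load_test: negative load at row %d",
                  which(df$load_N < 0)[1]), class = "crushcurve_io_error")
  }
  dd <- diff(df$displacement_mm)
  if (any(dd < -machine$disp_accuracy_mm)) {
    abort(sprintf(
      "read_load_test: displacement decreases beyond accuracy (%.3g mm) at row %d",
      machine$disp_accuracy_mm, which(dd < -machine$disp_accuracy_mm)[1] + 1L),
      class = "crushcurve_io_error")
  }
  new_crush_recording(df, machine = machine, nodule_id = nodule_id)
}

#' Write a recording to CSV
#'
#' Full-precision CSV with columns `time_ms`, `load_N`,
#' `displacement_mm`, reread identically by [read_load_test()].
#'
#' @param rec A recording tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(is.data.frame(rec))
  readr::write_csv(as_tibble(rec)[c("time_ms", "load_N", "displacement_mm")],
                   path)
  invisible(path)
}

#' Write a nodule metadata table
#'
#' @param nodules A nodule table (rows from [nodule_record()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nodule_table <- function(nodules, path) {
  cols <- intersect(c("nodule_id", "patient_id", "A0_mm2", "H0_mm", "V0_mm3",
                      "ct_hu", "dialysis", "cusp", "pattern_truth"),
                    names(nodules))
  readr::write_csv(nodules[cols], path)
  invisible(path)
}

#' Read a nodule metadata table
#'
#' @param path CSV with at least `nodule_id`, `A0_mm2`, `H0_mm`.
#' @return A validated nodule tibble (with `V0_mm3` recomputed).
#' @export
read_nodule_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("nodule_id", "A0_mm2", "H0_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("read_nodule_table: missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "crushcurve_io_error")
  }
  nodule_record(
    df$nodule_id, df$A0_mm2, df$H0_mm,
    patient_id = df$patient_id %||% NA_character_,
    ct_hu = df$ct_hu %||% NA_real_,
    dialysis = df$dialysis %||% NA,
    cusp = df$cusp %||% NA_character_,
    pattern_truth = df$pattern_truth %||% NA_character_
  )
}

#' Write the per-nodule results table
#'
#' One row per nodule: identifiers and covariates, CT density, CS and CE
#' at every level, and the crush-pattern classification. Column order is
#' deterministic and no timestamps are embedded, so repeated runs on the
#' same inputs are byte-identical.
#'
#' @param profiles Stiffness profiles ([stiffness_profile()] rows),
#'   optionally already joined with [classify_phase()] output.
#' @param records Nodule table keyed by `nodule_id`.
#' @param path Optional CSV path; if `NULL` the table is only returned.
#' @return The assembled tibble (invisibly if written).
#' @export
write_results <- function(profiles, records, path = NULL) {
  stopifnot(is.data.frame(profiles), is.data.frame(records))
  orphans <- setdiff(profiles$nodule_id, records$nodule_id)
  if (length(orphans)) {
    abort(paste0("write_results: profiles without matching nodule record: ",
                 paste(orphans, collapse = ", ")),
          class = "crushcurve_key_error")
  }
  res <- left_join(profiles, records, by = "nodule_id")
  lead <- intersect(c("nodule_id", "patient_id", "cusp", "dialysis",
                      "A0_mm2", "H0_mm", "V0_mm3", "ct_hu"), names(res))
  stiff <- grep("^C[SE][0-9]+$", names(res), value = TRUE)
  rest <- setdiff(names(res), c(lead, stiff))
  res <- res[c(lead, stiff, rest)]
  res <- res[order(res$nodule_id), ]
  if (!is.null(path)) {
    readr::write_csv(res, path)
    return(invisible(res))
  }
  res
}

#' Read a supplementary-style stiffness table
#'
#' Reads a per-nodule table carrying CS/CE columns (and optionally CT
#' density) from CSV or, when the `readxl` package is available, XLSX.
#' Column names are mapped onto the package's canonical names through
#' `col_map`, the escape hatch for externally produced layouts.
#'
#' @param path CSV or XLSX path.
#' @param col_map Named character vector, canonical = file name, e.g.
#'   `c(CS10 = "CS 10%", ct_hu = "mean CT number")`.
#' @param sheet Sheet index or name for XLSX input.
#' @return A tibble with canonical column names where mapped.
#' @export
read_supplementary <- function(path, col_map = NULL, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("read_supplementary: reading XLSX requires the 'readxl' package",
            class = "crushcurve_io_error")
    }
    as_tibble(readxl::read_excel(path, sheet = sheet))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(df)) names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  df
}
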