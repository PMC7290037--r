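#' Read a time-series trace from delimited text
#'
#' Expects a header with columns `time_s` and `value` (comma- or
#' tab-separated, inferred from the extension). Times must be strictly
#' increasing; parse errors report the offending data line.
#'
#' @param path Path to a CSV/TSV file.
#' @return A raw-trace tibble (`time`, `value`).
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- suppressWarnings(
    reader(path, col_types = readr::cols(.default = readr::col_character()),
           progress = FALSE))
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("missing required columns `time_s`, `value` in ", path, call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(t) | !is.finite(v))
  if (length(bad) > 0) {
    stop("non-numeric cell in ", path, " at data line ", bad[1], call. = FALSE)
  }
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono) > 0) {
    stop("times not strictly increasing in ", path, " at data line ",
         nonmono[1] + 1, call. = FALSE)
  }
  tibble::tibble(time = t, value = v)
}

#' Write a time-series trace as CSV
#'
#' Columns `time_s`, `value`, 12 significant digits.
#'
#' @param series Series tibble (`time`, `value`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path) {
  series <- check_series_frame(series)
  readr::write_csv(tibble::tibble(time_s = signif(series$time, 12),
                                  value = signif(series$value, 12)),
                   path, progress = FALSE)
  invisible(path)
}

#' Read trial metadata from a JSON sidecar
#'
#' @param path Path to a JSON file with at least `stimulus_onset_s`,
#'   `stimulus_duration_s` and `acquisition_len_s`.
#' @return A named list.
#' @export
read_trial_meta <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("stimulus_onset_s", "stimulus_duration_s", "acquisition_len_s")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("trial metadata missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Serialize transfer-function parameters to JSON
#'
#' Writes the four parameters plus optional provenance metadata (signal
#' kinds, stimulus label, seed, configuration fingerprint).
#'
#' @param params A [tf_params].
#' @param path Output path.
#' @param meta Named list of extra fields (e.g. `from`, `to`, `stimulus`,
#'   `seed`).
#' @return The path, invisibly.
#' @export
write_tf <- function(params, path, meta = list()) {
  params <- as_tf_params(params)
  payload <- c(unclass(params), meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read transfer-function parameters from JSON
#'
#' @param path Path written by [write_tf()].
#' @return A [tf_params] object; extra fields are kept in
#'   `attr(, "meta")`.
#' @export
read_tf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("p1", "p2", "p3", "p4")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0) {
    stop("TF file ", path, " missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  params <- tf_params(obj$p1, obj$p2, obj$p3, obj$p4)
  attr(params, "meta") <- obj[setdiff(names(obj), need)]
  params
}
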