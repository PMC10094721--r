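# Tabular/JSON report writers.  CSV for descriptor series (columns
# frame_id, value, unit; one file per series name), JSON for structured
# reports, plus a manifest with checksums so a rerun can be verified
# byte-for-byte.

#' Write descriptor series and reports to a directory
#'
#' Each distinct series name becomes `<name>.csv` with columns
#' `frame_id`, `value`, `unit` (full precision); each named report
#' becomes `<name>.json`.  A `manifest.json` lists every file with its
#' MD5 checksum.  Re-reading a written series reproduces its values
#' exactly.
#'
#' @param series A [lox_series()] tibble (several series may be bound by
#'   row), or `NULL`.
#' @param reports Named list of JSON-serialisable report objects, or
#'   `NULL`.
#' @param out_dir Output directory (created if missing).
#' @return Tibble manifest: `file`, `md5`, invisibly.
#' @export
write_report <- function(series = NULL, reports = NULL, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", out_dir))
  }
  files <- character(0)
  if (!is.null(series) && nrow(series) > 0) {
    for (nm in unique(series$name)) {
      sub <- series[series$name == nm, c("frame_id", "value", "unit")]
      # 17 significant digits: exact binary round-trip for doubles
      sub$value <- sprintf("%.17g", sub$value)
      path <- file.path(out_dir, paste0(nm, ".csv"))
      readr::write_csv(sub, path)
      files <- c(files, path)
    }
  }
  for (nm in names(reports)) {
    path <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(reports[[nm]], path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(files, path)
  }
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a descriptor-series CSV written by [write_report()]
#'
#' @param path Path to a series CSV.
#' @param name Series name; defaults to the file stem.
#' @return A [lox_series()].
#' @export
read_report_series <- function(path, name = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(value = "c"))
  # base-R strtod gives the exactly-rounded double for the written digits
  lox_series(name %||% sub("\\.csv$", "", basename(path)),
             tbl$frame_id, as.numeric(tbl$value), tbl$unit[1])
}
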