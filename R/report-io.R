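report_num_cols <- c("e_min", "e_mean", "delta_g", "com_x", "com_y", "com_z")

#' Write a rescoring report to disk
#'
#' Field order is fixed and all real numbers are rendered with 4 decimal
#' places, so repeated runs produce byte-identical, diffable output. The
#' JSON format additionally embeds the run parameters, which makes the
#' report self-describing and re-runnable.
#'
#' @param report A `rescore_report` from [rescore_poses()]/[rank_report()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_report_json()]
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  if (!inherits(report, "rescore_report")) abort("not a rescore_report")
  if (nrow(report$entries) == 0) abort("empty report")
  if (!is.character(format) || !all(format %in% c("tsv", "json"))) {
    abort(paste0("unknown report format: ", format[1]))
  }
  format <- match.arg(format)
  entries <- report$entries
  if (format == "tsv") {
    out <- dplyr::mutate(entries, dplyr::across(
      dplyr::all_of(report_num_cols), ~ sprintf("%.4f", .x)))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    payload <- list(
      parameters = report$parameters,
      entries = dplyr::mutate(entries, dplyr::across(
        dplyr::all_of(report_num_cols), ~ round(.x, 4)))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a JSON rescoring report
#'
#' Inverse of [write_report()] with `format = "json"`: reconstructs the
#' `rescore_report`, exact at the report's stated 4-decimal precision.
#'
#' @param path Path to a JSON report.
#' @return A `rescore_report`.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$entries)) abort(paste0("not a report: ", path))
  entries <- as_tibble(payload$entries)
  entries$cluster_rank <- as.integer(entries$cluster_rank)
  entries$n_poses <- as.integer(entries$n_poses)
  entries$representative_pose <- as.integer(entries$representative_pose)
  structure(list(entries = entries,
                 parameters = as.list(payload$parameters)),
            class = "rescore_report")
}
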