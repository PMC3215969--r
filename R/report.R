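# Report writers: TSV tables (full precision, unit-suffixed headers), JSON
# reports and the run manifest that makes every result reproducible.

#' Write / read a result table as TSV
#'
#' Numeric columns are written with 15 significant digits so tables
#' round-trip losslessly at the precision the solver works at. Headers may
#' carry unit suffixes (e.g. `growth_rate_per_hr`); they are preserved
#' verbatim.
#'
#' @param x a data frame (envelope, SPEEQ grid, flux table, ...).
#' @param path output path.
#' @return `path` invisibly; `read_report_tsv()` returns a tibble.
#' @export
write_report_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write a structured JSON report
#'
#' @param x a list or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records what a run was computed with: model checksum (md5 of the
#' canonical JSON serialization), solver identity and tolerances, package
#' version and timestamp. The pipeline is deterministic, so re-running with
#' an identical manifest (timestamp aside) reproduces outputs bit for bit.
#'
#' @param model an `efba_model`.
#' @param extra optional named list of run parameters to record.
#' @return A list; write it with [write_report_json()].
#' @export
run_manifest <- function(model, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_model(model, tmp, format = "json")
  c(list(
    model_id = model$id,
    model_md5 = unname(tools::md5sum(tmp)),
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    solver = "electrofba bounded-variable simplex",
    tolerance_optimality = 1e-9,
    tolerance_feasibility = 1e-7,
    package_version = as.character(utils::packageVersion("electrofba")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
}
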