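#' Write a trial log to disk
#'
#' Trial logs are serialised either as RFC-4180 CSV (comma separator, "."
#' decimal, header fixed to the standard column order) or as JSON lines
#' (one trial object per line). dB-valued columns are written at 4 decimal
#' places so logs are byte-stable across platforms.
#'
#' @param trials A trial-log `data.frame` (see [run_session()]).
#' @param path Output file; the format is inferred from the extension
#'   (`.csv` or `.jsonl`) unless `format` is given.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, format = NULL) {
  check_trial_log(trials)
  format <- infer_format(path, format)
  extra <- setdiff(names(trials), trial_log_columns)
  out <- trials[, c(trial_log_columns, extra)]
  for (cl in c("level", "internal_value", "criterion_used",
               intersect(extra, "session_level")))
    out[[cl]] <- round(out[[cl]], 4)
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     na = "")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(out, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads a CSV or JSON-lines trial log and validates it row by row:
#' required columns present, enumerated fields within their vocabulary,
#' and outcomes consistent with trial type and response. Malformed rows
#' are reported with their row numbers.
#'
#' @param path File written by [write_trial_log()] (or produced elsewhere
#'   in the same schema).
#' @param format `"csv"` or `"jsonl"`; inferred from the extension by
#'   default.
#' @return The validated trial-log `data.frame`.
#' @export
read_trial_log <- function(path, format = NULL) {
  format <- infer_format(path, format)
  trials <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  check_trial_log(trials)
  for (cl in c("is_correction", "rewarded", "centre_reward"))
    trials[[cl]] <- as.logical(trials[[cl]])
  if (is.character(trials$level)) trials$level <- as.numeric(trials$level)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("malformed trial log '", path, "': ", what, " at row(s) ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) sprintf(" (and %d more)",
                                          length(rows) - 10) else "")
  }
  bad(!trials$trial_type %in% c("signal", "nosignal"),
      "invalid trial_type")
  bad(!trials$response %in% c("yes", "no"), "invalid response")
  bad(!trials$outcome %in% c("hit", "miss", "correct_rejection",
                             "false_alarm"), "invalid outcome")
  bad(trials$trial_type == "signal" & !is.finite(trials$level),
      "signal trial without a level")
  expected <- ifelse(trials$trial_type == "signal",
                     ifelse(trials$response == "yes", "hit", "miss"),
                     ifelse(trials$response == "yes", "false_alarm",
                            "correct_rejection"))
  bad(trials$outcome != expected,
      "outcome inconsistent with trial_type and response")
  bad(trials$rewarded != (trials$outcome %in%
                            c("hit", "correct_rejection")),
      "rewarded flag inconsistent with outcome")
  trials
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "jsonl")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv")) "csv"
  else if (ext %in% c("jsonl", "ndjson")) "jsonl"
  else stop("cannot infer trial-log format from extension '.", ext,
            "'; pass `format`")
}

#' Read a run configuration file
#'
#' Configurations are plain YAML or JSON mappings; the format is inferred
#' from the extension.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be YAML or JSON, got '.", ext, "'")
}

#' Write a run configuration file
#'
#' @param config A named list.
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(config, path)
  else if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  else stop("config must be YAML or JSON, got '.", ext, "'")
  invisible(path)
}

#' Serialise analysis results to JSON
#'
#' Writes psychometric results, dependency trees, fit evaluations or any
#' plain list structure as JSON (unboxed scalars, full precision).
#'
#' @param x The object; S3 classes used by this package are converted to
#'   plain lists/data.frames first.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)[
    !vapply(unclass(x), is.function, logical(1))]))
  if (inherits(x, "lm")) return(NULL)
  if (is.list(x)) {
    x <- unclass(x)
    out <- lapply(x, strip_classes)
    out[!vapply(out, is.null, logical(1))]
  } else x
}

#' Export per-SNR dependency differences as CSV
#'
#' Writes the after-correct-rejection minus after-hit P(yes) differences
#' (the points of the level-dependence regression) to a CSV file.
#'
#' @param tree A [build_dependency_tree()] result.
#' @param path Output `.csv` file.
#' @return `path`, invisibly.
#' @export
write_dependency_csv <- function(tree, path) {
  sl <- dependency_slope(tree)
  utils::write.csv(sl$points, path, row.names = FALSE)
  invisible(path)
}
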