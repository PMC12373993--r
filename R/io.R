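# CSV interchange, flat key-value configuration and run metadata.

growth_csv_header <- base::c("individual_id", "scenario", "time_days",
                             "length_mm", "neonates")

#' Read a growth dataset from CSV
#'
#' Reads a long-format growth CSV with header `individual_id, scenario,
#' time_days, length_mm, neonates` (one row per observation event; lines
#' starting with `#` are metadata comments and are skipped). Lengths
#' recorded in micrometres are converted to millimetres when
#' `length_unit = "um"`. Unknown extra columns are dropped with a warning;
#' duplicate (individual, time) records and nonmonotone times are errors
#' naming the offending file row.
#'
#' @param path Path to the CSV file.
#' @param length_unit `"mm"` (default) or `"um"`.
#' @param col_map Optional named character vector adapting a foreign
#'   schema: names are the standard column names, values the file's column
#'   names, e.g. `c(individual_id = "animal", time_days = "age_d")`.
#'   Unmapped standard columns are read under their own names.
#' @return A validated [growth_dataset()].
#' @export
read_growth_csv <- function(path, length_unit = c("mm", "um"),
                            col_map = NULL) {
  length_unit <- match.arg(length_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), growth_csv_header)
    if (length(bad))
      stop("'col_map' names must be standard columns; unknown: ",
           paste(bad, collapse = ", "))
    missing_src <- setdiff(unname(col_map), names(df))
    if (length(missing_src))
      stop("'col_map' refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    for (std in names(col_map)) df[[std]] <- df[[col_map[[std]]]]
    df <- df[setdiff(names(df), setdiff(unname(col_map),
                                        growth_csv_header))]
  }
  extra <- setdiff(names(df), growth_csv_header)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[setdiff(names(df), extra)]
  }
  missing_cols <- setdiff(growth_csv_header, names(df))
  if (length(missing_cols))
    stop("header must contain columns: ",
         paste(growth_csv_header, collapse = ", "),
         " (missing: ", paste(missing_cols, collapse = ", "), ")")
  if (length_unit == "um") df$length_mm <- df$length_mm / 1000
  # report file rows (header is row 1) rather than data-frame rows
  tryCatch(growth_dataset(df), error = function(e) {
    msg <- conditionMessage(e)
    m <- regmatches(msg, regexpr("row [0-9]+", msg))
    if (length(m)) {
      n <- as.integer(sub("row ", "", m)) + 1L
      msg <- sub("row [0-9]+", paste("row", n), msg)
    }
    stop(msg, call. = FALSE)
  })
}

#' Write a growth dataset to CSV
#'
#' Writes the standard growth CSV schema, preceded by `#`-prefixed
#' metadata comment lines when supplied.
#'
#' @param dataset A [growth_dataset()].
#' @param path Output path.
#' @param meta Optional named character/list of metadata to embed as
#'   comments.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(dataset, path, meta = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_block(con, meta)
  utils::write.csv(as.data.frame(dataset)[growth_csv_header], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_meta_block <- function(con, meta) {
  if (is.null(meta)) return(invisible(NULL))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")),
               con)
  invisible(NULL)
}

#' Run metadata block
#'
#' Deterministic provenance attached to every output file: package version,
#' the seed, the configuration values in effect and md5 checksums of the
#' input files.
#'
#' @param inputs Character vector of input file paths (may be empty).
#' @param config Named list of configuration values.
#' @param seed Seed used, or `NA`.
#' @return Named character vector suitable for the `meta` argument of the
#'   writers.
#' @export
run_metadata <- function(inputs = character(0), config = list(),
                         seed = NA) {
  meta <- base::c(
    package = paste("allogrow",
                    as.character(utils::packageVersion("allogrow"))),
    seed = as.character(seed))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    meta <- base::c(meta, stats::setNames(
      paste(basename(inputs), unname(sums)), rep("input", length(inputs))))
  }
  if (length(config))
    meta <- base::c(meta, stats::setNames(
      vapply(config, function(v) paste(format(v), collapse = " "),
             character(1)),
      paste0("config.", names(config))))
  meta
}

#' Default run configuration
#'
#' The tunable settings of the fitting pipeline with their defaults:
#' `grid_step` 0.5 day, `loess_span` 0.75, `r_span` 0.5, a `lambda` grid
#' from 0 to 0.6 in steps of 0.01, 200 bootstrap replicates, lengths in mm
#' and a cubic mass--length exponent.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(grid_step = 0.5, loess_span = 0.75, r_span = 0.5,
       lambda_min = 0, lambda_max = 0.6, lambda_step = 0.01,
       bootstrap_B = 200, seed = NA, length_unit = "mm", k = 3)
}

#' Read a flat key-value configuration file
#'
#' Parses a TOML-style flat file of `key = value` lines (comments with `#`,
#' blank lines ignored). Values that parse as numbers become numeric;
#' everything else stays character. Keys not present fall back to
#' [default_config()].
#'
#' @param path Path to the configuration file, or `NULL` for the defaults.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  config <- default_config()
  if (is.null(path)) return(config)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
  }
  config
}

lambda_grid_from_config <- function(config) {
  if (config$lambda_max <= config$lambda_min)
    stop("empty lambda grid: lambda_max must exceed lambda_min")
  seq(config$lambda_min, config$lambda_max, by = config$lambda_step)
}

#' Write a ground-truth sidecar file
#'
#' Flat `label.field = value` lines recording the generator truth of each
#' scenario, so recovery tests can be run against a written dataset.
#'
#' @param truths Named list of [scenario_truth()] objects (or one truth).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truths, path) {
  if (inherits(truths, "scenario_truth"))
    truths <- stats::setNames(list(truths), truths$label)
  lines <- character(0)
  for (label in names(truths)) {
    tr <- truths[[label]]
    for (f in setdiff(names(tr), "label"))
      lines <- base::c(lines, sprintf("%s.%s = %s", label, f,
                                      format(tr[[f]], digits = 12)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a fit result as structured text
#'
#' Flat `key = value` lines: the shared exponent, per-scenario `q`, the
#' residual scale and the objective value, plus bootstrap intervals when
#' present.
#'
#' @param fit A `growth_fit`.
#' @param path Output path.
#' @param meta Optional metadata block (written as `#` comments).
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, meta = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_block(con, meta)
  fmt <- function(x) format(x, digits = 12)
  lines <- base::c(sprintf("lambda_hat = %s", fmt(fit$lambda_hat)),
                   sprintf("sigma_hat = %s", fmt(fit$sigma_hat)),
                   sprintf("sse = %s", fmt(fit$sse)))
  for (sc in names(fit$q_hat))
    lines <- base::c(lines, sprintf("q_hat.%s = %s", sc,
                                    fmt(fit$q_hat[[sc]])))
  if (!is.null(fit$ci)) {
    lines <- base::c(lines,
                     sprintf("lambda_ci = %s %s", fmt(fit$ci$lambda[1]),
                             fmt(fit$ci$lambda[2])))
    for (sc in rownames(fit$ci$q))
      lines <- base::c(lines, sprintf("q_ci.%s = %s %s", sc,
                                      fmt(fit$ci$q[sc, 1]),
                                      fmt(fit$ci$q[sc, 2])))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write the fitted r_t curves as CSV
#'
#' One row per (scenario, grid time): the fitted reproduction-investment
#' rate `r_t` and the implied gradient coefficient `f = q (1 - r_t)`.
#'
#' @inheritParams write_fit_result
#' @return `path`, invisibly.
#' @export
write_r_curves <- function(fit, path, meta = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  rows <- do.call(rbind, lapply(names(fit$r_hat), function(sc) {
    data.frame(scenario = sc, time_days = fit$r_hat[[sc]]$times,
               r_hat = fit$r_hat[[sc]]$r,
               f_implied = fit$q_hat[[sc]] * (1 - fit$r_hat[[sc]]$r))
  }))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_block(con, meta)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
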