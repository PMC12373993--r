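# Long-format individual growth records: one row per observation event
# (birth, each brood, death), uneven times, per-individual.

#' Construct and validate a growth dataset
#'
#' A growth dataset is a long-format data frame of individual observation
#' events with columns `individual_id`, `scenario`, `time_days`, `length_mm`
#' and `neonates`. Each individual is observed at birth (time 0), at each
#' brood (where `neonates` records the brood size) and at death; `neonates`
#' is `NA` at non-brood events. The last observation time of an individual
#' is taken as its death time.
#'
#' @param x A data frame with the columns above.
#'
#' @return `x` with class `growth_dataset` prepended, after validation.
#' @export
growth_dataset <- function(x) {
  required <- base::c("individual_id", "scenario", "time_days", "length_mm",
                      "neonates")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$individual_id <- as.character(x$individual_id)
  x$scenario <- as.character(x$scenario)
  x$time_days <- as.numeric(x$time_days)
  x$length_mm <- as.numeric(x$length_mm)
  x$neonates <- as.numeric(x$neonates)

  if (any(!is.finite(x$time_days)) || any(x$time_days < 0))
    stop("'time_days' must be finite and nonnegative")
  if (any(!is.finite(x$length_mm)) || any(x$length_mm <= 0))
    stop("'length_mm' must be positive")
  nn <- x$neonates[!is.na(x$neonates)]
  if (any(nn < 0) || any(nn != round(nn)))
    stop("'neonates' must be nonnegative integers (or NA at non-brood events)")

  key <- paste(x$individual_id, x$time_days)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop(sprintf("duplicate (individual, time) record at row %d (id '%s', t = %g)",
                 row, x$individual_id[row], x$time_days[row]))
  }
  for (id in unique(x$individual_id)) {
    idx <- which(x$individual_id == id)
    tt <- x$time_days[idx]
    if (is.unsorted(tt, strictly = TRUE)) {
      row <- idx[which(diff(tt) <= 0)[1] + 1L]
      stop(sprintf("times for individual '%s' are not strictly increasing at row %d",
                   id, row))
    }
    if (tt[1] != 0)
      stop(sprintf("individual '%s' has no birth (time 0) record", id))
    if (length(unique(x$scenario[idx])) != 1L)
      stop(sprintf("individual '%s' appears under more than one scenario", id))
  }
  class(x) <- base::c("growth_dataset", "data.frame")
  x
}

#' @export
print.growth_dataset <- function(x, ...) {
  ids <- unique(x$individual_id)
  cat(sprintf("Growth dataset: %d observations, %d individuals, %d scenario(s)\n",
              nrow(x), length(ids), length(unique(x$scenario))))
  tab <- table(x$scenario[!duplicated(x$individual_id)])
  for (s in names(tab)) cat(sprintf("  %-18s %d individuals\n", s, tab[[s]]))
  invisible(x)
}

#' Per-individual death times
#'
#' The death time of each individual is its last observation time.
#'
#' @param dataset A [growth_dataset()].
#' @param scenario Optional scenario label to restrict to.
#' @return Named numeric vector of death times (days), one per individual.
#' @export
death_times <- function(dataset, scenario = NULL) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (!is.null(scenario)) {
    dataset <- dataset[dataset$scenario == scenario, , drop = FALSE]
    if (!nrow(dataset)) stop("no individuals in scenario '", scenario, "'")
  }
  vapply(split(dataset$time_days, dataset$individual_id), max, numeric(1))
}
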