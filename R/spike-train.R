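#' Construct a spike train
#'
#' A spike train holds the sorted spike timestamps of a single neuron over one
#' recording, together with its identifiers. Timestamps are stored in seconds;
#' interspike intervals are reported downstream in milliseconds.
#'
#' @param timestamps Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.
#' @param cell_id Character scalar identifying the cell.
#' @param duration Recording length in seconds. All parameter estimates in
#'   this package assume 30-s recordings; see [validate_train()].
#' @param mouse_id,group_label Optional metadata. `group_label` is the origin
#'   cohort of the cell (e.g. `"control"`, `"ataxia"`, `"dystonia"`,
#'   `"tremor"`, or any other cohort name); it is carried as data and never
#'   inferred from file names.
#' @return An object of class `"spike_train"`.
#' @seealso [validate_train()], [featurize()], [isi_ms()]
#' @export
#' @examples
#' st <- spike_train(seq(0.01, 29.99, by = 0.01), cell_id = "c1")
#' st
spike_train <- function(timestamps, cell_id = "cell", duration = 30,
                        mouse_id = NA_character_, group_label = NA_character_) {
  timestamps <- as.numeric(timestamps)
  if (is.unsorted(timestamps, strictly = FALSE)) timestamps <- sort(timestamps)
  st <- structure(
    list(cell_id = as.character(cell_id),
         mouse_id = as.character(mouse_id),
         group_label = as.character(group_label),
         timestamps = timestamps,
         duration = as.numeric(duration)),
    class = "spike_train")
  st
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s, %s): %d spikes / %.6g s\n",
              x$cell_id, x$mouse_id, x$group_label,
              length(x$timestamps), x$duration))
  invisible(x)
}

#' Validate a spike train against the recording invariants
#'
#' Violations are returned as data, not raised as errors: an empty character
#' vector means the train satisfies every rule. Checked rules: strictly
#' increasing timestamps (no duplicates), all timestamps within
#' `[0, duration]`, positive duration, at least 2 spikes (required for any
#' ISI-based statistic), and -- when `require_30s` is set -- a duration of
#' exactly 30 s, since recording duration biases every parameter estimate.
#'
#' @param train A [spike_train()].
#' @param require_30s Require `duration == 30` (the default, matching the
#'   recording protocol all thresholds were derived under).
#' @param tol Numeric tolerance for the duration comparison.
#' @return Character vector of violated rules (empty if valid).
#' @export
#' @examples
#' validate_train(spike_train(c(0.1, 0.1), duration = 30))
validate_train <- function(train, require_30s = TRUE, tol = 1e-9) {
  stopifnot(inherits(train, "spike_train"))
  v <- character()
  ts <- train$timestamps
  if (!is.numeric(train$duration) || length(train$duration) != 1 ||
      is.na(train$duration) || train$duration <= 0)
    v <- c(v, "duration must be a positive scalar")
  if (require_30s && is.finite(train$duration) &&
      abs(train$duration - 30) > tol)
    v <- c(v, "duration != 30 s")
  if (length(ts) < 2)
    v <- c(v, "fewer than 2 spikes")
  if (anyNA(ts))
    v <- c(v, "missing timestamp")
  if (length(ts) >= 2 && any(diff(ts) == 0))
    v <- c(v, "duplicate timestamp")
  if (length(ts) >= 2 && any(diff(ts) < 0))
    v <- c(v, "timestamps not increasing")
  if (length(ts) >= 1 && !anyNA(ts) &&
      (min(ts) < 0 || max(ts) > train$duration + tol))
    v <- c(v, "timestamp outside [0, duration]")
  v
}

#' Collect spike trains into a cohort table
#'
#' @param trains List of [spike_train()] objects with unique `cell_id`s.
#' @param provenance Free-text description of where the data came from.
#' @return An object of class `"cohort_table"`.
#' @export
cohort_table <- function(trains, provenance = "") {
  stopifnot(is.list(trains),
            all(vapply(trains, inherits, logical(1), "spike_train")))
  ids <- vapply(trains, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids))
    stop("duplicate cell_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trains) <- ids
  structure(list(trains = trains, provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  gl <- vapply(x$trains, `[[`, character(1), "group_label")
  cat(sprintf("<cohort_table> %d trains", length(x$trains)))
  if (!all(is.na(gl))) {
    tb <- table(gl, useNA = "no")
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.cohort_table <- function(x) length(x$trains)

#' Interspike intervals in milliseconds
#'
#' @param train A [spike_train()], or a numeric vector of timestamps in
#'   seconds.
#' @return Numeric vector of interspike intervals, ms; length is one less
#'   than the number of spikes.
#' @export
#' @examples
#' isi_ms(spike_train(c(0.010, 0.020, 0.040)))  # 10, 20
isi_ms <- function(train) {
  ts <- if (inherits(train, "spike_train")) train$timestamps else
    as.numeric(train)
  if (length(ts) < 2)
    stop("insufficient data: at least 2 spikes are required for ISIs")
  diff(ts) * 1000
}
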