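#' Mean firing rate
#'
#' Spike count divided by the recording duration, in spikes/s. The count is
#' not reduced by one: an empty train has rate 0.
#'
#' @param train A [spike_train()].
#' @return Firing rate, spikes/s.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration <= 0) stop("zero or negative duration")
  length(train$timestamps) / train$duration
}

#' Instantaneous firing rate statistics
#'
#' The instantaneous firing rate (IFR) of an interval is its reciprocal with
#' the ISI expressed in seconds, so IFRs are in Hz. `median_ifr()` uses the
#' midpoint of the two central order statistics for even counts (the
#' conventional sample median).
#'
#' @param isis Numeric vector of interspike intervals in milliseconds.
#' @return Mean (or median) of `1/ISI`, Hz.
#' @export
mean_ifr <- function(isis) {
  if (length(isis) < 1) stop("insufficient data: empty ISI sequence")
  mean(1 / (isis / 1000))
}

#' @rdname mean_ifr
#' @export
median_ifr <- function(isis) {
  if (length(isis) < 1) stop("insufficient data: empty ISI sequence")
  stats::median(1 / (isis / 1000))
}

#' Coefficient of variation of the ISI distribution
#'
#' Sample standard deviation (n - 1 denominator) over the mean. Sensitive to
#' slow rate drift across the recording, unlike [isi_cv2()].
#'
#' @param isis ISIs in ms (at least 2).
#' @return Dimensionless CV, `>= 0`.
#' @export
isi_cv <- function(isis) {
  if (length(isis) < 2) stop("insufficient data: need at least 2 ISIs")
  stats::sd(isis) / mean(isis)
}

#' CV2, the local irregularity of consecutive ISI pairs
#'
#' Mean over consecutive pairs of `2 |ISI_n - ISI_{n-1}| / (ISI_n +
#' ISI_{n-1})`. Because each term compares neighbours only, CV2 is largely
#' immune to slow firing-rate drift; values lie in `[0, 2)`.
#'
#' @param isis ISIs in ms (at least 2).
#' @return Dimensionless CV2 in `[0, 2)`.
#' @export
isi_cv2 <- function(isis) {
  if (length(isis) < 2) stop("insufficient data: need at least 2 ISIs")
  n <- length(isis)
  mean(2 * abs(isis[-1] - isis[-n]) / (isis[-1] + isis[-n]))
}

#' Skewness index of the instantaneous-rate distribution
#'
#' `2 (median IFR - firing rate) / (median IFR + firing rate)`: a bounded
#' (-2, 2) contrast between the typical instantaneous rate and the mean
#' rate. Bursty trains, whose median instantaneous rate far exceeds the mean
#' rate, score high; regular trains score near zero.
#'
#' @param median_ifr Median instantaneous firing rate, Hz.
#' @param firing_rate Mean firing rate, spikes/s.
#' @return Dimensionless value in (-2, 2).
#' @export
skewness_index <- function(median_ifr, firing_rate) {
  s <- median_ifr + firing_rate
  if (!is.finite(s) || s <= 0) stop("skewness undefined: rate sum is not positive")
  2 * (median_ifr - firing_rate) / s
}

#' Percentage of ISIs strictly above a threshold
#'
#' @param isis ISIs in ms.
#' @param threshold_ms Threshold in ms (25 and 100 are the standard values:
#'   instantaneous rate below 40 Hz and 10 Hz respectively).
#' @return Percent in `[0, 100]`.
#' @export
isi_fraction_above <- function(isis, threshold_ms) {
  if (length(isis) < 1) stop("insufficient data: empty ISI sequence")
  100 * mean(isis > threshold_ms)
}

#' Mean inter-burst pause duration
#'
#' Mean of all ISIs exceeding five times the overall mean ISI; 0 when no
#' interval qualifies (a value unambiguously outside the attainable range of
#' qualifying means, keeping feature tables dense).
#'
#' @param isis ISIs in ms.
#' @return Pause duration, ms (0 if none).
#' @export
interburst_pause <- function(isis) {
  if (length(isis) < 1) stop("insufficient data: empty ISI sequence")
  cutoff <- 5 * mean(isis)
  q <- isis[isis > cutoff]
  if (length(q) == 0) 0 else mean(q)
}

#' Modal-bin mass of the ISI distribution
#'
#' ISIs are histogrammed in 1-ms bins `[k, k+1)`; the returned value is the
#' percentage of ISIs falling in the most populated bin (ties resolved to
#' the smallest bin edge). A perfectly regular train concentrates all mass
#' in one bin and scores 100.
#'
#' @param isis ISIs in ms.
#' @return Percent in `(0, 100]`.
#' @export
mode_fraction <- function(isis) {
  if (length(isis) < 1) stop("insufficient data: empty ISI sequence")
  bins <- floor(isis + 1e-9)   # 1-ns guard: periodic trains stay in one bin
  tb <- table(bins)
  100 * max(tb) / length(isis)
}

#' Compute the twelve spike-train parameters of one cell
#'
#' Composition of the individual parameter functions plus the
#' autocorrelogram rhythmicity analysis; deterministic given the train.
#'
#' @param train A valid [spike_train()] with at least 2 spikes.
#' @param require_30s Enforce the 30-s recording rule (default). Pass
#'   `FALSE` to featurize other durations at your own risk; estimates are
#'   duration-sensitive.
#' @return Named numeric vector with the entries of [feature_names()].
#' @export
#' @examples
#' featurize(spike_train(seq(0.005, 29.995, by = 0.01)))
featurize <- function(train, require_30s = TRUE) {
  v <- validate_train(train, require_30s = require_30s)
  if (length(v)) stop("invalid train ", train$cell_id, ": ",
                      paste(v, collapse = "; "))
  isis <- isi_ms(train)
  fr <- firing_rate(train)
  mifr <- median_ifr(isis)
  ac <- autocorrelogram(train)
  ry <- rhythmicity(ac, mean_isi_ms = mean(isis))
  c(firing_rate = fr,
    mean_ifr = mean_ifr(isis),
    median_ifr = mifr,
    cv = isi_cv(isis),
    cv2 = isi_cv2(isis),
    skewness = skewness_index(mifr, fr),
    isi25 = isi_fraction_above(isis, 25),
    isi100 = isi_fraction_above(isis, 100),
    interburst_pause = interburst_pause(isis),
    mode_fraction = mode_fraction(isis),
    rhythmicity_index = ry$rhythmicity_index,
    oscillation_peaks = ry$oscillation_peaks)
}

#' Featurize every train of a cohort
#'
#' @param cohort A [cohort_table()].
#' @param require_30s See [featurize()].
#' @return Data frame: `cell_id`, `group_label`, then the twelve features.
#' @export
featurize_cohort <- function(cohort, require_30s = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- lapply(cohort$trains, function(tr) {
    f <- featurize(tr, require_30s = require_30s)
    cbind(data.frame(cell_id = tr$cell_id, group_label = tr$group_label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
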