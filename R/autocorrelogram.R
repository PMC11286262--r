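#' Spike-train autocorrelogram
#'
#' Counts ordered spike pairs (i < j) whose forward lag falls in 5-ms bins
#' up to 1 s. Only positive lags are kept (the negative half is redundant)
#' and counts are raw, since the downstream acceptance thresholds are
#' count-relative. The `baseline` is the mean bin count over the 960-1000 ms
#' tail window and `tail_sd` its standard deviation: the tail is the only
#' lag region treated as a rhythm-free reference, so its scatter estimates
#' the counting noise against which oscillation peaks are judged.
#'
#' @param train A [spike_train()] with at least 2 spikes.
#' @param bin_ms Bin width, ms (5).
#' @param max_lag_ms Largest lag considered, ms (1000).
#' @param tail_window Two-element vector, ms: the reference window.
#' @return An object of class `"autocorrelogram"`: list with `bin_width`,
#'   `lags` (bin left edges, ms), `counts`, `baseline`, `tail_sd`,
#'   `n_spikes`.
#' @export
autocorrelogram <- function(train, bin_ms = 5, max_lag_ms = 1000,
                            tail_window = c(960, 1000)) {
  ts <- if (inherits(train, "spike_train")) train$timestamps else
    as.numeric(train)
  n <- length(ts)
  if (n < 2) stop("insufficient data: at least 2 spikes required")
  max_lag <- max_lag_ms / 1000
  nbins <- as.integer(round(max_lag_ms / bin_ms))
  counts <- numeric(nbins)
  # pair lags accumulated by spike offset k; stops once all lags exceed 1 s
  for (k in seq_len(n - 1)) {
    lags <- ts[(1 + k):n] - ts[1:(n - k)]
    lags <- lags[lags < max_lag]
    if (length(lags) == 0) break
    idx <- floor(lags * 1000 / bin_ms) + 1
    tab <- tabulate(idx, nbins)
    counts <- counts + tab
  }
  lags_ms <- (seq_len(nbins) - 1) * bin_ms
  in_tail <- lags_ms >= tail_window[1] & lags_ms < tail_window[2]
  structure(list(bin_width = bin_ms, lags = lags_ms, counts = counts,
                 baseline = mean(counts[in_tail]),
                 tail_sd = stats::sd(counts[in_tail]),
                 n_spikes = n),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf(
    "<autocorrelogram> %d bins x %g ms, n_spikes %d, baseline %.2f, tail sd %.2f\n",
    length(x$counts), x$bin_width, x$n_spikes, x$baseline, x$tail_sd))
  invisible(x)
}

#' Rhythmicity index and oscillation peaks from an autocorrelogram
#'
#' Iterative alternating peak/trough detection. The first peak is the
#' highest bin with left edge between 10 ms and 1.5 times the mean ISI
#' (ties to the smallest lag). The trough paired with a peak at lag L is the
#' lowest bin in `(L, L + L1]` where L1 is the first peak's lag; the next
#' peak is searched in `(lag of previous trough, lag of previous peak + L1 +
#' 10 ms]`. A peak/trough pair is accepted if the peak height above baseline
#' plus the trough depth below baseline exceeds four tail standard
#' deviations, or if the peak exceeds baseline + 2 SD while the trough falls
#' below baseline - 2 SD. Detection stops at the first rejected pair or when
#' a search window runs past the 1-s autocorrelogram.
#'
#' The rhythmicity index is the accepted sum `\eqn{\sum_i (a_i + b_i) / z}`
#' with `z = |n_spikes - baseline|`; `oscillation_peaks` counts the accepted
#' peaks.
#'
#' @param ac An [autocorrelogram()].
#' @param mean_isi_ms Mean ISI of the train, ms (sets the first-peak
#'   window).
#' @return List: `rhythmicity_index`, `oscillation_peaks`, `peaks` and
#'   `troughs` data frames (lag, count, height/depth, accepted), `flagged`
#'   (TRUE when the first-peak window is empty, i.e. 1.5 x mean ISI <= 10
#'   ms, in which case the index is 0 with 0 peaks).
#' @export
rhythmicity <- function(ac, mean_isi_ms) {
  stopifnot(inherits(ac, "autocorrelogram"))
  if (!is.finite(mean_isi_ms) || mean_isi_ms <= 0)
    stop("mean_isi_ms must be positive")
  lags <- ac$lags; counts <- ac$counts
  bl <- ac$baseline; sdv <- ac$tail_sd
  z <- abs(ac$n_spikes - bl)
  empty <- data.frame(lag = numeric(), count = numeric(),
                      delta = numeric(), accepted = logical())
  res <- list(rhythmicity_index = 0, oscillation_peaks = 0L,
              peaks = empty, troughs = empty, flagged = FALSE)

  upper1 <- 1.5 * mean_isi_ms
  win <- which(lags >= 10 & lags <= upper1)
  if (length(win) == 0) { res$flagged <- TRUE; return(res) }

  pk_rows <- tr_rows <- list()
  total <- 0; npk <- 0L
  L1 <- NA_real_
  peak_lag <- NA_real_
  repeat {
    i_pk <- win[which.max(counts[win])]   # ties: smallest lag (first max)
    peak_lag <- lags[i_pk]
    if (is.na(L1)) L1 <- peak_lag
    a <- counts[i_pk] - bl
    twin <- which(lags > peak_lag & lags <= peak_lag + L1)
    if (length(twin) == 0) break          # window beyond 1 s: stop
    i_tr <- twin[which.min(counts[twin])]
    b <- bl - counts[i_tr]
    ok <- (a + b) > 4 * sdv ||
      (counts[i_pk] > bl + 2 * sdv && counts[i_tr] < bl - 2 * sdv)
    pk_rows[[length(pk_rows) + 1]] <-
      data.frame(lag = peak_lag, count = counts[i_pk], delta = a,
                 accepted = ok)
    tr_rows[[length(tr_rows) + 1]] <-
      data.frame(lag = lags[i_tr], count = counts[i_tr], delta = b,
                 accepted = ok)
    if (!ok) break                        # stop at first rejected pair
    total <- total + a + b
    npk <- npk + 1L
    win <- which(lags > lags[i_tr] & lags <= peak_lag + L1 + 10)
    if (length(win) == 0) break
  }
  res$rhythmicity_index <- if (z > 0) total / z else 0
  res$oscillation_peaks <- npk
  res$peaks <- do.call(rbind, c(pk_rows, list(empty)))
  res$troughs <- do.call(rbind, c(tr_rows, list(empty)))
  res
}
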