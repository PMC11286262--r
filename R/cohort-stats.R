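#' Two-proportion z-test (pooled, no continuity correction)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`, and a two-sided normal p-value. No
#' continuity correction is applied. When the pooled proportion is 0 or 1
#' the statistic is degenerate and 0 is returned with a warning.
#'
#' @param x1,n1 Successes and size of the first sample.
#' @param x2,n2 Successes and size of the second sample.
#' @return List with `z` and `p.value` (plus the two proportions).
#' @export
#' @examples
#' two_proportion_z(15, 23, 7, 21)  # z = 2.1128
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  if (p <= 0 || p >= 1) {
    warning("pooled proportion is degenerate (0 or 1); z set to 0")
    return(list(z = 0, p.value = 1, p1 = p1, p2 = p2, pooled = p))
  }
  z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       pooled = p)
}

#' One-vs-rest enrichment chi-square for a signature within an origin group
#'
#' Collapses the cohort summary to the 2 x 2 table
#' (origin == `origin_group` vs other) x (signature == `signature` vs
#' other) and applies the df-1 chi-square test without continuity
#' correction. Identical to the square of the pooled two-proportion z on
#' the same counts.
#'
#' @param summary A [classify_cohort()] result (`cohort_summary`), or a
#'   counts matrix with origin rows and signature columns.
#' @param origin_group Row (origin cohort) of interest.
#' @param signature Column (assigned signature) of interest.
#' @return List with `chi2`, `p.value` and the collapsed 2 x 2 `table`.
#' @export
enrichment_chi_square <- function(summary, origin_group, signature) {
  counts <- if (inherits(summary, "cohort_summary")) summary$counts else
    as.matrix(summary)
  if (sum(counts) == 0) stop("empty summary table")
  if (!origin_group %in% rownames(counts))
    stop("unknown origin group: ", origin_group)
  if (!signature %in% colnames(counts))
    stop("unknown signature: ", signature)
  in_g <- rownames(counts) == origin_group
  in_s <- colnames(counts) == signature
  tab <- matrix(c(sum(counts[in_g, in_s]), sum(counts[in_g, !in_s]),
                  sum(counts[!in_g, in_s]), sum(counts[!in_g, !in_s])),
                2, 2, byrow = TRUE,
                dimnames = list(origin = c(origin_group, "other"),
                                signature = c(signature, "other")))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd == 0)) stop("expected count of zero in the 2 x 2 table")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), p.value = unname(ht$p.value),
       table = tab)
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Standard one-way ANOVA over named groups followed by Tukey's honest
#' significant differences; [stats::TukeyHSD()] applies the Tukey-Kramer
#' adjustment for unequal group sizes, with p-values from the studentized
#' range distribution. Degenerate all-identical data returns F = 0 and
#' adjusted p-values of 1 rather than NaN.
#'
#' @param groups Named list of numeric vectors (one per group, each of
#'   length >= 2).
#' @return List: `F`, `p.value`, and `tukey` data frame with `comparison`,
#'   `diff` and `p_adj`.
#' @export
#' @examples
#' anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12)))
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)), all(nzchar(names(groups))))
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  prs <- utils::combn(names(groups), 2)
  comparison <- paste(prs[2, ], prs[1, ], sep = "-")
  if (stats::var(value) == 0) {
    return(list(F = 0, p.value = 1,
                tukey = data.frame(comparison = comparison,
                                   diff = 0, p_adj = 1)))
  }
  fit <- stats::aov(value ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  list(F = an[["F value"]][1], p.value = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL))
}

#' Construct an accelerometer trace object
#'
#' @param samples Acceleration samples, arbitrary units.
#' @param sampling_rate Sampling rate, Hz (> 60 so the 0-30 Hz band is
#'   resolved).
#' @return Object of class `"accel_trace"`.
#' @export
accel_trace <- function(samples, sampling_rate) {
  if (sampling_rate <= 60)
    stop("sampling_rate must exceed 60 Hz to resolve the 0-30 Hz band")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate),
            class = "accel_trace")
}

#' Peak tremor power from an accelerometer trace
#'
#' Mean-removed, Hann-windowed one-sided periodogram; the spectrum is
#' normalized so the summed power approximates the signal variance
#' (Parseval). The peak is the maximum power at frequencies in `(0, 30]`
#' Hz (the DC bin is excluded), with its frequency.
#'
#' @param trace An [accel_trace()].
#' @return List: `peak_power`, `peak_frequency_hz`, and the `spectrum` data
#'   frame (`frequency`, `power`).
#' @export
tremor_peak_power <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  if (trace$duration < 2) stop("trace must be at least 2 s long")
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))   # Hann
  X <- stats::fft(x * w)
  half <- seq(2, floor(n / 2) + 1)            # positive frequencies
  power <- 2 * Mod(X[half])^2 / (n * sum(w^2))
  freq <- (half - 1) * trace$sampling_rate / n
  band <- freq > 0 & freq <= 30
  if (!any(band)) stop("no frequency bins in (0, 30] Hz")
  k <- which(band)[which.max(power[band])]
  list(peak_power = power[k], peak_frequency_hz = freq[k],
       spectrum = data.frame(frequency = freq, power = power))
}

#' Row-normalized signature proportions
#'
#' @param summary A `cohort_summary` or counts matrix.
#' @return Matrix of row proportions (each row sums to 1). All-zero rows
#'   are returned as zeros and flagged in the `"zero_rows"` attribute.
#' @export
proportion_table <- function(summary) {
  counts <- if (inherits(summary, "cohort_summary")) summary$counts else
    as.matrix(summary)
  if (length(counts) == 0) stop("empty summary table")
  rs <- rowSums(counts)
  out <- counts / ifelse(rs == 0, 1, rs)
  attr(out, "zero_rows") <- rownames(counts)[rs == 0]
  out
}
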