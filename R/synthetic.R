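## ---- internal simulators ---------------------------------------------------

## slow sinusoidal firing-rate modulation via time rescaling: spikes are laid
## down in operational time and mapped through the inverse of the cumulative
## rate, so local ISI statistics (CV2) are preserved while the overall ISI
## distribution is broadened (CV) -- the signature of awake-state rate drift.
.warp_sinusoid <- function(ts_op, depth, period, phase, duration) {
  if (depth <= 0) return(ts_op[ts_op <= duration])
  g <- seq(0, duration, by = 0.001)
  tau <- g - (depth * period / (2 * pi)) *
    (cos(2 * pi * g / period + phase) - cos(phase))
  out <- stats::approx(tau, g, xout = ts_op[ts_op <= max(tau)], rule = 2)$y
  out[out <= duration]
}

## gamma-renewal ISIs with an optional pause mixture component and slow drift
.sim_renewal_mixture <- function(shape, mean_ms, pause_prob, pause_shape,
                                 pause_mean_ms, mod_depth, mod_period,
                                 duration) {
  mean_mix <- (1 - pause_prob) * mean_ms + pause_prob * pause_mean_ms
  n <- ceiling(duration * 1000 / mean_mix * 1.7) + 80
  pick <- stats::runif(n) < pause_prob
  isi <- ifelse(pick,
                stats::rgamma(n, pause_shape, scale = pause_mean_ms / pause_shape),
                stats::rgamma(n, shape, scale = mean_ms / shape))
  ts <- cumsum(isi) / 1000
  .warp_sinusoid(ts, mod_depth, mod_period, stats::runif(1, 0, 2 * pi),
                 duration)
}

## cycle process for rhythmic bursting: one burst per cycle (skipped with
## probability p_skip), intra-burst ISIs gamma-distributed with
## geometrically growing means (burst deceleration), accumulating period
## jitter so the autocorrelogram rhythm decays towards the 1-s tail
.sim_cycle_burst <- function(freq_hz, burst_lambda, p_skip, isi_base_ms,
                             isi_growth, isi_shape, jitter_sd_ms, duration) {
  period <- 1000 / freq_hz
  ts <- numeric(0)
  t0 <- stats::runif(1, 0, period / 1000)
  while (t0 < duration) {
    if (stats::runif(1) > p_skip) {
      nb <- 1 + stats::rpois(1, burst_lambda)
      sp <- if (nb > 1) {
        means <- isi_base_ms * isi_growth^(0:(nb - 2))
        t0 + c(0, cumsum(stats::rgamma(nb - 1, isi_shape,
                                       scale = means / isi_shape))) / 1000
      } else t0
      ts <- c(ts, sp[sp < duration])
    }
    t0 <- t0 + (period + stats::rnorm(1, 0, jitter_sd_ms)) / 1000
  }
  sort(ts)
}

## ---- per-phenotype parameter draws ----------------------------------------

## Each cell draws its parameters from calibrated ranges: real cohorts show
## cell-to-cell heterogeneity, and without it most features would separate
## the phenotypes perfectly, which no real recording does. The "core"
## variant defines the archetypal regime; the named variants are the
## documented atypical cells that real cohorts contain (see the methods
## vignette for the rationale behind each).
.variant_table <- list(
  control = c("core", "irregular", "pausing"),
  ataxia = c("core", "drifting"),
  dystonia = c("core", "fast_bursting", "slow"),
  tremor = c("core", "slow_bursting", "no_skip"))

.draw_params <- function(phenotype, variant) {
  U <- function(a, b) stats::runif(1, a, b)
  key <- paste(phenotype, variant, sep = "/")
  switch(key,
    "control/core" = list(kind = "mixture", shape = U(2.4, 6),
      mean_ms = U(10.5, 15.5), pause_prob = U(0, 0.015), pause_shape = 2,
      pause_mean_ms = 50, mod_depth = U(0.25, 0.45), mod_period = U(8, 25)),
    "control/irregular" = list(kind = "mixture", shape = U(1.3, 1.6),
      mean_ms = U(9.5, 12), pause_prob = U(0, 0.01), pause_shape = 2,
      pause_mean_ms = 50, mod_depth = U(0.15, 0.35), mod_period = U(8, 25)),
    "control/pausing" = list(kind = "mixture", shape = U(3, 4.2),
      mean_ms = U(12, 13.5), pause_prob = U(0.004, 0.006), pause_shape = 2,
      pause_mean_ms = U(350, 450), mod_depth = U(0.1, 0.3),
      mod_period = U(8, 25)),
    "ataxia/core" = list(kind = "mixture", shape = U(40, 120),
      mean_ms = U(10.5, 14), pause_prob = 0, pause_shape = 2,
      pause_mean_ms = 50, mod_depth = U(0.05, 0.35), mod_period = U(8, 25)),
    "ataxia/drifting" = list(kind = "mixture", shape = U(50, 100),
      mean_ms = U(10.5, 13), pause_prob = 0, pause_shape = 2,
      pause_mean_ms = 50, mod_depth = U(0.65, 0.8), mod_period = U(8, 25)),
    "dystonia/core" = list(kind = "mixture", shape = U(1.2, 2.2),
      mean_ms = U(24, 30), pause_prob = U(0.13, 0.2), pause_shape = 2,
      pause_mean_ms = U(110, 160), mod_depth = U(0.05, 0.3),
      mod_period = U(8, 25)),
    "dystonia/fast_bursting" = list(kind = "mixture", shape = U(0.85, 1),
      mean_ms = U(14, 17), pause_prob = U(0.14, 0.18), pause_shape = 2,
      pause_mean_ms = U(140, 170), mod_depth = U(0.05, 0.2),
      mod_period = U(8, 25)),
    "dystonia/slow" = list(kind = "mixture", shape = U(1.2, 2.2),
      mean_ms = U(26, 30), pause_prob = U(0.12, 0.2), pause_shape = 2,
      pause_mean_ms = U(110, 160), mod_depth = U(0.05, 0.3),
      mod_period = U(8, 25)),
    "tremor/core" = {
      lam <- U(3.4, 5.5)
      list(kind = "burst", freq_hz = U(8.5, 10.5), burst_lambda = lam,
           p_skip = U(0.1, 0.4), isi_base_ms = U(4, 4 + 0.65 * lam),
           isi_growth = U(1.05, 1.35), isi_shape = U(3, 6),
           jitter_sd_ms = 8)
    },
    "tremor/slow_bursting" = list(kind = "burst", freq_hz = U(8.5, 9),
      burst_lambda = U(4.8, 5.2), p_skip = U(0.55, 0.65),
      isi_base_ms = U(16.5, 18.5), isi_growth = 1,
      isi_shape = U(14, 18), jitter_sd_ms = 8),
    "tremor/no_skip" = list(kind = "burst", freq_hz = U(10, 10.5),
      burst_lambda = U(6, 7), p_skip = 0, isi_base_ms = U(3.5, 4.5),
      isi_growth = U(1, 1.1), isi_shape = U(5, 7), jitter_sd_ms = 8),
    stop("unknown phenotype/variant: ", key))
}

.expected_rate <- function(p) {
  if (p$kind == "mixture") {
    1000 / ((1 - p$pause_prob) * p$mean_ms + p$pause_prob * p$pause_mean_ms)
  } else {
    p$freq_hz * (1 + p$burst_lambda) * (1 - p$p_skip)
  }
}

## ---- public API ------------------------------------------------------------

#' Generate one synthetic spike train of a given phenotype
#'
#' Core generators per phenotype: control and ataxia are gamma-renewal
#' processes (moderately irregular vs. very regular) under slow sinusoidal
#' rate drift; dystonia is a slow two-component mixture renewal (irregular
#' firing interrupted by long pauses); tremor is a ~10 Hz cycle process
#' firing decelerating bursts with accumulating period jitter. The `variant`
#' argument exposes the atypical cell types that [generate_archetypal_cohort()]
#' mixes into each cohort.
#'
#' @param phenotype One of `"control"`, `"ataxia"`, `"dystonia"`,
#'   `"tremor"`.
#' @param duration Recording length, s (30).
#' @param seed Integer seed; when supplied the draw is reproducible.
#' @param variant Cell variant; `"core"` (default) is the archetypal
#'   regime. See Details.
#' @param cell_id,mouse_id Identifiers for the returned train.
#' @return A [spike_train()] with `group_label = phenotype` and the drawn
#'   parameters attached as attribute `"params"` (including the seed).
#' @export
#' @examples
#' tr <- generate_train("ataxia", seed = 1)
#' featurize(tr)[c("cv2", "skewness")]
generate_train <- function(phenotype = c("control", "ataxia", "dystonia",
                                         "tremor"),
                           duration = 30, seed = NULL, variant = "core",
                           cell_id = NULL, mouse_id = NA_character_) {
  phenotype <- match.arg(phenotype)
  if (!variant %in% .variant_table[[phenotype]])
    stop("unknown variant '", variant, "' for phenotype ", phenotype)
  if (!is.null(seed)) set.seed(seed)
  p <- .draw_params(phenotype, variant)
  if (.expected_rate(p) * duration < 2)
    stop("parameters imply fewer than 2 expected spikes")
  ts <- if (p$kind == "mixture") {
    .sim_renewal_mixture(p$shape, p$mean_ms, p$pause_prob, p$pause_shape,
                         p$pause_mean_ms, p$mod_depth, p$mod_period,
                         duration)
  } else {
    .sim_cycle_burst(p$freq_hz, p$burst_lambda, p$p_skip, p$isi_base_ms,
                     p$isi_growth, p$isi_shape, p$jitter_sd_ms, duration)
  }
  if (length(ts) < 2) stop("generated fewer than 2 spikes")
  tr <- spike_train(ts,
                    cell_id = if (is.null(cell_id))
                      sprintf("%s_%s", phenotype, variant) else cell_id,
                    duration = duration, mouse_id = mouse_id,
                    group_label = phenotype)
  attr(tr, "params") <- c(p, list(variant = variant, seed = seed))
  tr
}

#' Cohort composition used by the archetypal generator
#'
#' Fractions of atypical cell variants per cohort; the remainder are core
#' cells. They mirror the within-cohort heterogeneity of real recordings:
#' most notably, a noticeable minority of tremor-cohort cells carry a
#' dystonia-like slow irregular signature.
#'
#' @return Named list of `variant = fraction` vectors per phenotype.
#' @export
cohort_composition <- function() {
  list(control = c(irregular = 0.08, pausing = 0.04),
       ataxia = c(drifting = 0.10),
       dystonia = c(fast_bursting = 0.05),
       tremor = c(slow = 0.15,            # dystonia-like cells
                  slow_bursting = 0.05, no_skip = 0.05))
}

#' Generate a labeled archetypal cohort
#'
#' Draws `n_per_group` cells per phenotype, each with an independent
#' per-cell seed derived from the master seed (recorded in the train's
#' parameters), with the atypical-variant composition of
#' [cohort_composition()] (fractions rounded per cohort). The tremor
#' cohort's `slow` cells are drawn from the slow end of the dystonia
#' generator -- they are the cells a classifier confuses with dystonia.
#'
#' @param n_per_group Named integer vector (any subset of the four
#'   phenotypes, each >= 1).
#' @param seed Master seed.
#' @param duration Recording length, s.
#' @return List with `cohort` (a [cohort_table()]) and `labels` (character
#'   vector of origin phenotypes, one per train).
#' @export
generate_archetypal_cohort <- function(n_per_group = c(control = 25,
                                                       ataxia = 20,
                                                       dystonia = 20,
                                                       tremor = 20),
                                       seed = 1, duration = 30) {
  bad <- setdiff(names(n_per_group), names(.variant_table))
  if (length(bad)) stop("unknown group name(s): ", paste(bad, collapse = ", "))
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 for each group")
  set.seed(seed)
  total <- sum(n_per_group)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, total)
  comp <- cohort_composition()
  trains <- list(); labels <- character(); k <- 0L
  for (g in names(n_per_group)) {
    n <- n_per_group[[g]]
    variants <- character(0)
    for (v in names(comp[[g]]))
      variants <- c(variants, rep(v, max(0L, round(comp[[g]][[v]] * n))))
    if (g == "tremor") variants <- sub("^slow$", "dystonia_slow", variants)
    variants <- c(variants, rep("core", n - length(variants)))
    for (i in seq_len(n)) {
      k <- k + 1L
      v <- variants[i]
      tr <- if (identical(v, "dystonia_slow")) {
        generate_train("dystonia", duration = duration, seed = cell_seeds[k],
                       variant = "slow",
                       cell_id = sprintf("%s_%03d", g, i))
      } else {
        generate_train(g, duration = duration, seed = cell_seeds[k],
                       variant = v, cell_id = sprintf("%s_%03d", g, i))
      }
      tr$group_label <- g                  # origin label, not generator
      trains[[k]] <- tr
      labels[k] <- g
    }
  }
  list(cohort = cohort_table(trains,
                             provenance = sprintf("synthetic cohort, seed %d",
                                                  seed)),
       labels = labels)
}
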