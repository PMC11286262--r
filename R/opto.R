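#' Optogenetic light-stimulation waveforms
#'
#' The three paradigms used to drive Purkinje-cell terminals: ataxia -- a
#' continuous 50 Hz square pulse train (10 ms on / 10 ms off); dystonia --
#' blocks of at least 1 s of the 50 Hz train, each followed with 75%
#' probability by a 250 ms pause in stimulation; tremor -- a 100 Hz pulse
#' train (5 ms on / 5 ms off) amplitude-modulated by a 10 Hz envelope
#' (50 ms parabolic rise and fall of light power, then 50 ms off).
#'
#' @param paradigm `"ataxia_stim"`, `"dystonia_stim"` or `"tremor_stim"`.
#' @param duration Waveform length, s.
#' @param dt Sample step, s.
#' @param seed Seed for the dystonia pause sequence (the other paradigms
#'   are deterministic).
#' @return Data frame with `time` (s) and `light` (relative power in
#'   `[0, 1]`).
#' @export
opto_waveform <- function(paradigm = c("ataxia_stim", "dystonia_stim",
                                       "tremor_stim"),
                          duration = 30, dt = 5e-4, seed = NULL) {
  paradigm <- match.arg(paradigm)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration - dt, by = dt)
  light <- switch(paradigm,
    ataxia_stim = as.numeric((tt %% 0.02) < 0.01),
    dystonia_stim = {
      on <- numeric(length(tt))
      t0 <- 0
      while (t0 < duration) {
        on[tt >= t0 & tt < t0 + 1] <- 1
        t0 <- t0 + 1
        if (stats::runif(1) < 0.75) t0 <- t0 + 0.25
      }
      on * as.numeric((tt %% 0.02) < 0.01)
    },
    tremor_stim = {
      u <- tt %% 0.1
      env <- ifelse(u < 0.05, 1 - (u / 0.025 - 1)^2, 0)
      env * as.numeric((tt %% 0.01) < 0.005)
    })
  data.frame(time = tt, light = light)
}

## Synaptic integration of the light waveform into an effective inhibition
## drive: causal exponential filter (tau ~ GABAergic IPSC decay) followed by
## saturation at 15% of the sustained full-power drive (so pulse trains and most of the 10-Hz envelope drive inhibition at full depth). Pulse trains
## at 50-100 Hz therefore act as sustained inhibition, as observed when
## stimulating Purkinje-cell terminals; the tremor envelope survives as the
## modulating waveform.
.effective_inhibition <- function(light, dt, tau = 0.008, sat = 0.15) {
  a <- exp(-dt / tau)
  y <- stats::filter(light * (1 - a), filter = a, method = "recursive")
  pmin(1, as.numeric(y) / sat)
}

#' Spike train of a nuclei neuron under optogenetic inhibition
#'
#' A gamma-renewal process (shape `base_shape`, the control-like regime) is
#' generated in operational time and rescaled through the cumulative
#' instantaneous rate `r(t) = base_rate * (1 - gain * s(t))`, where `s(t)`
#' is the paradigm's effective inhibition drive (the light waveform after
#' synaptic integration and saturation; see [opto_waveform()]). At
#' `gain = 0` the train is statistically identical to the unmodulated base
#' process.
#'
#' @param base_rate_hz Baseline firing rate, spikes/s (> 0).
#' @param paradigm Stimulation paradigm, see [opto_waveform()].
#' @param gain Inhibition gain in `[0, 1]`; 1 silences the cell at full
#'   drive.
#' @param duration Recording length, s.
#' @param seed Seed (drives both the pause sequence and the renewal
#'   process).
#' @param base_shape Gamma shape of the baseline renewal process.
#' @param dt Waveform sample step, s.
#' @return A [spike_train()] with `group_label` set to the paradigm.
#' @export
opto_modulated_train <- function(base_rate_hz = 100,
                                 paradigm = c("ataxia_stim", "dystonia_stim",
                                              "tremor_stim"),
                                 gain = 0.9, duration = 30, seed = NULL,
                                 base_shape = 3, dt = 5e-4) {
  paradigm <- match.arg(paradigm)
  if (base_rate_hz <= 0) stop("base_rate_hz must be positive")
  if (gain < 0 || gain > 1) stop("gain must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  wf <- opto_waveform(paradigm, duration = duration, dt = dt)
  s_eff <- .effective_inhibition(wf$light, dt)
  rate <- base_rate_hz * (1 - gain * s_eff)
  cum <- c(0, cumsum(rate) * dt)
  grid <- c(wf$time, duration)
  total <- cum[length(cum)]
  n <- ceiling(total * 1.5) + 50
  isi_op <- stats::rgamma(n, base_shape, scale = 1 / base_shape)
  ts_op <- cumsum(isi_op)
  while (ts_op[length(ts_op)] < total) {
    isi_op <- stats::rgamma(n, base_shape, scale = 1 / base_shape)
    ts_op <- c(ts_op, ts_op[length(ts_op)] + cumsum(isi_op))
  }
  ts_op <- ts_op[ts_op <= total]
  ts <- stats::approx(cum, grid, xout = ts_op, rule = 2)$y
  spike_train(ts, cell_id = paste0(paradigm, "_cell"), duration = duration,
              group_label = paradigm)
}

#' Synthetic accelerometer trace for tremor power analysis
#'
#' A sinusoid of the given tremor frequency plus white Gaussian noise.
#'
#' @param tremor_hz Tremor frequency, Hz (< `sampling_rate / 2`).
#' @param amplitude Sine amplitude (0 gives pure noise).
#' @param noise_sd Noise standard deviation.
#' @param duration Trace length, s.
#' @param sampling_rate Sampling rate, Hz.
#' @param seed Seed.
#' @return An [accel_trace()].
#' @export
generate_accel_trace <- function(tremor_hz = 10, amplitude = 1,
                                 noise_sd = 0.1, duration = 30,
                                 sampling_rate = 500, seed = NULL) {
  if (tremor_hz >= sampling_rate / 2)
    stop("aliasing: tremor_hz must be below sampling_rate / 2")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  x <- amplitude * sin(2 * pi * tremor_hz * tt) +
    stats::rnorm(length(tt), 0, noise_sd)
  accel_trace(x, sampling_rate)
}
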