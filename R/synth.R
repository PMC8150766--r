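#' Configuration for the synthetic iEEG generator
#'
#' The generator emulates the two-class contrast the classifier is built for:
#' non-epileptogenic (NES) segments are stationary 1/f^beta background noise,
#' while epileptogenic (ES) segments superimpose interictal spike-like
#' transients (Ricker pulses) and band-limited high-frequency-oscillation
#' (HFO) bursts on the same background. Defaults describe an
#' interictal-recording-like contrast: unit-variance pink background
#' (beta = 1), spikes at 0.8 events/s with amplitude 3 background SDs,
#' ripple-band HFO bursts (80-150 Hz) at 0.5 events/s, and a small white
#' measurement-noise floor.
#'
#' @param sampling_rate sampling rate, Hz. Must exceed twice `hfo_band[2]`.
#' @param duration segment duration, s.
#' @param class_label `"ES"` or `"NES"`.
#' @param background_exponent beta of the 1/f^beta background spectrum.
#' @param spike_rate expected spike-wave transients per second (ES only).
#' @param spike_amplitude spike peak amplitude, in background-SD units.
#' @param hfo_band two-element numeric, HFO burst band `[low, high]` Hz.
#' @param hfo_burst_rate expected HFO bursts per second (ES only).
#' @param noise_sd SD of additive white measurement noise, signal units.
#' @param seed integer seed; identical configs give bitwise-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(sampling_rate = 512, duration = 20,
                         class_label = c("NES", "ES"),
                         background_exponent = 1,
                         spike_rate = 0.8, spike_amplitude = 3,
                         hfo_band = c(80, 150), hfo_burst_rate = 1,
                         noise_sd = 0.1, seed = 1L) {
  class_label <- match.arg(class_label)
  if (length(hfo_band) != 2 || hfo_band[1] <= 0 || hfo_band[2] <= hfo_band[1]) {
    abort("hfo_band must be c(low, high) with 0 < low < high")
  }
  if (sampling_rate <= 2 * hfo_band[2]) {
    abort("sampling_rate must exceed 2 * hfo_band[2] (Nyquist)")
  }
  if (duration <= 0) abort("duration must be > 0")
  if (spike_rate < 0 || hfo_burst_rate < 0) abort("event rates must be >= 0")
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         class_label = class_label,
         background_exponent = background_exponent,
         spike_rate = spike_rate, spike_amplitude = spike_amplitude,
         hfo_band = hfo_band, hfo_burst_rate = hfo_burst_rate,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f^beta Gaussian background synthesized in the frequency domain,
# normalized to unit SD.
synth_background <- function(n, fs, beta) {
  freqs <- seq_len(floor(n / 2)) * fs / n
  amp <- freqs^(-beta / 2)
  re <- rnorm(length(freqs))
  im <- rnorm(length(freqs))
  half <- complex(real = re, imaginary = im) * amp
  spec <- complex(length.out = n)
  spec[2:(length(freqs) + 1)] <- half
  if (n %% 2 == 0) spec[length(freqs) + 1] <- complex(real = re[length(freqs)] * amp[length(freqs)])
  idx_conj <- seq(n, by = -1, length.out = ceiling(n / 2) - 1)
  spec[idx_conj] <- Conj(spec[2:ceiling(n / 2)])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

# Mexican-hat (Ricker) pulse, peak amplitude 1, characteristic width a (s).
ricker_pulse <- function(t, a) {
  u <- t / a
  (1 - u^2) * exp(-u^2 / 2)
}

# Jittered event times at a given rate over [0, dur].
jittered_events <- function(rate, dur) {
  if (rate <= 0) return(numeric(0))
  n_exp <- rate * dur
  base <- seq(0.5 / rate, dur - 0.5 / rate, length.out = max(1, round(n_exp)))
  jit <- runif(length(base), -0.3 / rate, 0.3 / rate)
  pmin(pmax(base + jit, 0), dur)
}

#' Generate one synthetic iEEG segment
#'
#' @param cfg a [synth_config()].
#' @return An [new_segment()] with `duration * sampling_rate` samples and the
#'   configured label.
#' @examples
#' seg <- generate_segment(synth_config(duration = 2, class_label = "ES", seed = 7))
#' n_points(seg)
#' @export
generate_segment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, generate_segment_impl(cfg))
}

generate_segment_impl <- function(cfg) {
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  x <- synth_background(n, fs, cfg$background_exponent)
  if (cfg$class_label == "ES") {
    t_axis <- (seq_len(n) - 1) / fs
    # spike-wave transients: ~60 ms main lobe
    for (tc in jittered_events(cfg$spike_rate, cfg$duration)) {
      x <- x + cfg$spike_amplitude * ricker_pulse(t_axis - tc, a = 0.02)
    }
    # Gaussian-windowed sinusoid bursts inside the HFO band, ~100 ms
    for (tc in jittered_events(cfg$hfo_burst_rate, cfg$duration)) {
      f0 <- runif(1, cfg$hfo_band[1], cfg$hfo_band[2])
      phase <- runif(1, 0, 2 * pi)
      env <- exp(-((t_axis - tc) / 0.03)^2 / 2)
      x <- x + 2 * env * sin(2 * pi * f0 * (t_axis - tc) + phase)
    }
  }
  if (cfg$noise_sd > 0) x <- x + rnorm(n, sd = cfg$noise_sd)
  new_segment(x, fs = fs, label = cfg$class_label)
}

#' Generate a synthetic multi-lead SEEG-like session
#'
#' Produces one continuous recording per lead: the `n_epi` epileptogenic
#' leads draw from the ES generator, the remaining majority leads from the
#' NES generator. The minority epileptogenic class mirrors the clinical
#' lead imbalance the balance module equalizes.
#'
#' @param n_leads total number of leads.
#' @param n_epi number of epileptogenic leads; must be `< n_leads`.
#' @param dur per-lead duration, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param ... further arguments passed to [synth_config()] (contrast knobs).
#' @return An [new_recording()] with `lead_class` filled.
#' @export
generate_session <- function(n_leads, n_epi, dur = 60, fs = 512, seed = 1L, ...) {
  if (n_epi >= n_leads) abort("n_epi must be < n_leads (epileptogenic leads are the minority)")
  if (n_epi < 1) abort("n_epi must be >= 1")
  cls <- c(rep("epileptogenic", n_epi), rep("non-epileptogenic", n_leads - n_epi))
  lead_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_leads))
  samples <- matrix(0, nrow = n_leads, ncol = round(dur * fs))
  for (i in seq_len(n_leads)) {
    lab <- if (cls[i] == "epileptogenic") "ES" else "NES"
    cfg <- synth_config(sampling_rate = fs, duration = dur, class_label = lab,
                        seed = lead_seeds[i], ...)
    samples[i, ] <- generate_segment(cfg)$samples[1, ]
  }
  new_recording(samples, fs = fs, patient_id = sprintf("synth%d", seed),
                lead_ids = sprintf("L%03d", seq_len(n_leads)), lead_class = cls)
}
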