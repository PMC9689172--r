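#' Gaussian-modulated transmit pulse
#'
#' Builds the band-limited pulse used by the phantom simulator: a cosine
#' carrier at the transducer center frequency under a Gaussian envelope whose
#' -6 dB spectral width equals `frac_bandwidth * fc_hz`, sampled at `fs_hz`,
#' truncated at +/- 3 envelope standard deviations (odd length, symmetric
#' support) and scaled to unit peak amplitude.
#'
#' @param fc_hz Center frequency in Hz (default 3e6).
#' @param fs_hz Sampling frequency in Hz (default 12e6). Must satisfy
#'   Nyquist: `fc_hz < fs_hz / 2`.
#' @param frac_bandwidth Fractional -6 dB bandwidth (default 0.6).
#' @return An object of class `us_pulse`: list with `waveform` (odd-length
#'   numeric vector), `fc_hz`, `fs_hz`, `frac_bandwidth`, and `sigma_t`
#'   (envelope standard deviation in seconds).
#' @examples
#' p <- make_pulse()
#' length(p$waveform) %% 2  # odd support
#' @export
make_pulse <- function(fc_hz = 3e6, fs_hz = 12e6, frac_bandwidth = 0.6) {
  if (fc_hz <= 0 || fs_hz <= 0 || frac_bandwidth <= 0)
    stop("pulse parameters must be positive")
  if (fc_hz >= fs_hz / 2)
    stop(sprintf("aliasing: fc = %.3g Hz violates Nyquist at fs = %.3g Hz",
                 fc_hz, fs_hz))
  # -6 dB full spectral width 2*sqrt(2 log 2)*sigma_f = frac_bandwidth * fc
  sigma_f <- frac_bandwidth * fc_hz / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3 * sigma_t * fs_hz)
  t <- (-half:half) / fs_hz
  w <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc_hz * t)
  structure(list(waveform = w / max(abs(w)), fc_hz = fc_hz, fs_hz = fs_hz,
                 frac_bandwidth = frac_bandwidth, sigma_t = sigma_t),
            class = "us_pulse")
}

#' Pulse resolution-cell length in samples
#'
#' The axial resolution cell is defined as the pulse's -6 dB envelope
#' duration: the span over which the Gaussian envelope exceeds half its peak,
#' `2*sqrt(2*log(2)) * sigma_t * fs`. Scatterer densities in [stage_params()]
#' are expressed per this cell, which keeps the envelope-statistics regime
#' (pre-Rayleigh vs Rayleigh) directly controllable.
#'
#' @param pulse A [make_pulse()] object.
#' @return Cell length in samples (numeric, not rounded).
#' @export
resolution_cell_samples <- function(pulse) {
  stopifnot(inherits(pulse, "us_pulse"))
  2 * sqrt(2 * log(2)) * pulse$sigma_t * pulse$fs_hz
}

#' Stage-dependent scatterer parameters
#'
#' Maps a METAVIR stage to the parameters of the scatterer ensemble that the
#' phantom draws: the mean number of scatterers per pulse resolution cell and
#' the standard deviation of the zero-mean Gaussian scatterer amplitudes.
#' The defaults, density `2 + 3*stage` and amplitude SD `1 + 0.25*stage`,
#' increase jointly with stage as a conventional quantitative-ultrasound
#' surrogate for fibrosis-related microstructural change, moving the envelope
#' statistics from a sparse pre-Rayleigh regime (F0) towards fully developed
#' Rayleigh speckle with higher echogenicity (F4).
#'
#' @param stage Integer METAVIR stage 0-4.
#' @param scatterer_density Mean scatterers per resolution cell.
#' @param amplitude_sd Scatterer amplitude standard deviation.
#' @return An object of class `stage_params`.
#' @export
stage_params <- function(stage,
                         scatterer_density = 2 + 3 * stage,
                         amplitude_sd = 1 + 0.25 * stage) {
  stage <- as.integer(stage)
  if (is.na(stage) || stage < 0L || stage > 4L)
    stop("stage must be an integer in 0..4")
  if (scatterer_density <= 0 || amplitude_sd <= 0)
    stop("scatterer_density and amplitude_sd must be positive")
  structure(list(stage = stage,
                 scatterer_density = as.numeric(scatterer_density),
                 amplitude_sd = as.numeric(amplitude_sd)),
            class = "stage_params")
}

#' Phantom simulation configuration
#'
#' Frame geometry and pulse parameters for the synthetic scanner. Defaults
#' mirror the emulated clinical scanner: 1247 axial samples, 256 A-lines,
#' 12 MHz sampling, 3 MHz center frequency.
#'
#' @param n_axial Axial samples per A-line.
#' @param n_lines A-lines per frame.
#' @param fs_hz,fc_hz Sampling and center frequency in Hz.
#' @param frac_bandwidth Fractional -6 dB pulse bandwidth.
#' @param stage_map Function stage -> [stage_params()]; defaults to
#'   [stage_params()] itself.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_axial = 1247L, n_lines = 256L,
                       fs_hz = 12e6, fc_hz = 3e6, frac_bandwidth = 0.6,
                       stage_map = stage_params) {
  n_axial <- as.integer(n_axial); n_lines <- as.integer(n_lines)
  if (n_axial < 1L || n_lines < 1L) stop("frame dimensions must be positive")
  structure(list(n_axial = n_axial, n_lines = n_lines, fs_hz = fs_hz,
                 fc_hz = fc_hz, frac_bandwidth = frac_bandwidth,
                 stage_map = stage_map),
            class = "sim_config")
}

# FFT-based "same" convolution of every column of `imp` with kernel `h`
# (odd length). Equivalent to convolve(col, rev(h), type = "open") trimmed
# to the central nrow(imp) samples.
conv_same_cols <- function(imp, h) {
  L <- nrow(imp); P <- length(h)
  nfft <- stats::nextn(L + P - 1L, 2L)
  Fi <- stats::mvfft(rbind(imp, matrix(0, nfft - L, ncol(imp))))
  Fh <- stats::fft(c(h, numeric(nfft - P)))
  full <- Re(stats::mvfft(Fi * Fh, inverse = TRUE)) / nfft
  full[(P - 1L) / 2L + seq_len(L), , drop = FALSE]
}

#' Simulate one RF frame from a scatterer ensemble
#'
#' Each A-line draws a Poisson number of point scatterers (mean =
#' `scatterer_density * n_axial / resolution_cell_samples(pulse)`), places
#' them uniformly over depth with zero-mean Gaussian amplitudes, and
#' convolves the sparse impulse train with the transmit pulse ("same"
#' length). The result is band-limited speckle whose envelope statistics
#' shift with the stage parameters. Fully reproducible for a fixed seed.
#'
#' @param params A [stage_params()] object.
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed fixing all randomness in the frame.
#' @return An [rf_frame()] with `case_id` of the form `"sim_F<stage>"`.
#' @examples
#' f <- simulate_frame(stage_params(0), sim_config(n_axial = 256, n_lines = 8), seed = 1)
#' dim(f$samples)
#' @export
simulate_frame <- function(params, config = sim_config(), seed = 1L) {
  stopifnot(inherits(params, "stage_params"), inherits(config, "sim_config"))
  pulse <- make_pulse(config$fc_hz, config$fs_hz, config$frac_bandwidth)
  lambda <- params$scatterer_density * config$n_axial /
    resolution_cell_samples(pulse)
  L <- config$n_axial; M <- config$n_lines
  imp <- matrix(0, L, M)
  with_seed(seed, {
    ns <- stats::rpois(M, lambda)
    tot <- sum(ns)
    if (tot > 0L) {
      line <- rep.int(seq_len(M), ns)
      pos <- sample.int(L, tot, replace = TRUE)
      amp <- stats::rnorm(tot, 0, params$amplitude_sd)
      acc <- rowsum(amp, pos + (line - 1L) * L)
      imp[as.integer(rownames(acc))] <- acc
    }
  })
  rf <- if (sum(imp != 0) == 0L) imp else conv_same_cols(imp, pulse$waveform)
  rf_frame(rf, fs_hz = config$fs_hz, fc_hz = config$fc_hz,
           case_id = sprintf("sim_F%d", params$stage))
}

#' Simulate a labelled cohort of RF frames
#'
#' Writes one frame file per case (via [write_rf_frame()]) plus a manifest
#' CSV, and returns the cohort. Default stage counts reproduce the emulated
#' study population of 230 cases: F0 = 23, F1 = 46, F2 = 51, F3 = 49,
#' F4 = 61. Per-case sub-seeds are derived deterministically from the master
#' seed, so two runs with the same seed produce identical files.
#'
#' @param stage_counts Named integer vector, names "0".."4", cases per stage.
#' @param config A [sim_config()].
#' @param seed Master RNG seed.
#' @param out_dir Output directory (created if missing).
#' @return The cohort `data.frame` (columns `case_id`, `stage`, `frame_path`),
#'   also written to `file.path(out_dir, "manifest.csv")`.
#' @export
simulate_cohort <- function(stage_counts = default_stage_counts(),
                            config = sim_config(), seed = 1L,
                            out_dir) {
  stage_counts <- stage_counts[stage_counts > 0]
  stages <- as.integer(names(stage_counts))
  if (anyNA(stages) || any(stages < 0L | stages > 4L) || any(stage_counts < 0))
    stop("stage_counts must be named by stages 0..4 with non-negative counts")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list(); k <- 0L
  for (s in seq_along(stages)) {
    pars <- config$stage_map(stages[s])
    for (i in seq_len(stage_counts[s])) {
      k <- k + 1L
      case_id <- sprintf("F%d_%03d", stages[s], i)
      sub_seed <- (as.numeric(seed) + 7919 * k) %% .Machine$integer.max
      fr <- simulate_frame(pars, config, seed = as.integer(sub_seed))
      fr$case_id <- case_id
      path <- file.path(out_dir, paste0(case_id, ".f32"))
      write_rf_frame(fr, path)
      rows[[k]] <- data.frame(case_id = case_id, stage = stages[s],
                              frame_path = path, stringsAsFactors = FALSE)
    }
  }
  cohort <- as_cohort(do.call(rbind, rows))
  write_cohort_manifest(cohort, file.path(out_dir, "manifest.csv"))
  cohort
}

#' Default per-stage case counts of the emulated cohort
#'
#' @return Named integer vector `c("0"=23, "1"=46, "2"=51, "3"=49, "4"=61)`.
#' @export
default_stage_counts <- function() {
  c("0" = 23L, "1" = 46L, "2" = 51L, "3" = 49L, "4" = 61L)
}

# Evaluate `expr` under a temporary RNG seed, restoring any prior RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
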