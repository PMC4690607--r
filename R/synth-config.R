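#' Per-condition generator configuration
#'
#' Describes one treatment condition of the synthetic study: its spontaneous
#' beat rate and the distribution of the pulse-shape parameters across cells
#' (recordings) and beats. Parameter variance is split hierarchically: a
#' fraction `variance_split` of each parameter's variance is a cell-level
#' mean shift (shared by all beats of one recording), the remainder is
#' independent beat-to-beat jitter.
#'
#' @param label Condition name (e.g. "control", "propranolol",
#'   "isoproterenol").
#' @param beat_rate_mean,beat_rate_sd Spontaneous beat rate (beats/min).
#' @param pulse_mean A [pulse_params()] object giving the mean pulse shape.
#' @param pulse_sd Named numeric vector of standard deviations for
#'   `amplitude`, `rise`, `plateau`, `fall`, `plateau_end_frac` (any subset;
#'   missing entries default to 0).
#' @param variance_split Fraction of variance at the cell level, in [0, 1].
#' @param n_waveforms Total number of waveforms to generate for this
#'   condition in [simulate_feature_table()].
#' @return An object of class `condition_config`.
#' @export
condition_config <- function(label, beat_rate_mean, beat_rate_sd,
                             pulse_mean, pulse_sd = c(),
                             variance_split = 0.5, n_waveforms = 100L) {
  stopifnot(is.character(label), length(label) == 1L, beat_rate_mean > 0,
            beat_rate_sd >= 0, inherits(pulse_mean, "pulse_params"),
            variance_split >= 0, variance_split <= 1, n_waveforms > 0)
  sd_full <- c(amplitude = 0, rise = 0, plateau = 0, fall = 0,
               plateau_end_frac = 0)
  if (length(pulse_sd)) {
    stopifnot(!is.null(names(pulse_sd)),
              all(names(pulse_sd) %in% names(sd_full)), all(pulse_sd >= 0))
    sd_full[names(pulse_sd)] <- pulse_sd
  }
  structure(list(label = label, beat_rate_mean = beat_rate_mean,
                 beat_rate_sd = beat_rate_sd, pulse_mean = pulse_mean,
                 pulse_sd = sd_full, variance_split = variance_split,
                 n_waveforms = as.integer(n_waveforms)),
            class = "condition_config")
}

#' Full synthetic-study configuration
#'
#' Bundles the per-condition configurations with the imaging model: line-scan
#' geometry, membrane point-spread width, beat-coupled motion, the
#' double-exponential photobleaching curve `a*exp(b*t) + c*exp(d*t)`
#' (exponents `b`, `d` <= 0, units 1/s), and the noise model.
#'
#' @param conditions List of [condition_config()] objects.
#' @param n_recordings Recordings (cells) simulated per condition.
#' @param n_lines Lines per recording.
#' @param line_period Seconds per line.
#' @param pixels_per_line Pixels per line (>= 8; 128 matches typical
#'   two-photon line-scan acquisition).
#' @param n_membranes Membranes crossed by the scan line (1-5 typical).
#' @param psf_sigma Gaussian half-width of a membrane profile (px).
#' @param motion_amplitude Peak beat-coupled motion excursion (px).
#' @param motion_tau Low-pass time constant coupling motion to the beat
#'   train (s).
#' @param bleach Named numeric `c(a=, b=, c=, d=)` of the photobleaching
#'   double exponential (a, c in fluorescence counts; b, d <= 0 in 1/s).
#' @param noise_sd Additive Gaussian noise sd (counts).
#' @param noise_model "gaussian" (default) or "poisson" (photon-count
#'   shot noise; `noise_sd` is then ignored).
#' @param baseline_offset Constant background added to every pixel (counts).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(conditions, n_recordings = 5L, n_lines = 60000L,
                         line_period = 0.001, pixels_per_line = 128L,
                         n_membranes = 2L, psf_sigma = 2,
                         motion_amplitude = 2, motion_tau = 0.1,
                         bleach = c(a = 2500, b = -0.01, c = 1500, d = -5e-4),
                         noise_sd = 30,
                         noise_model = c("gaussian", "poisson"),
                         baseline_offset = 50) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, TRUE, "condition_config")),
            n_lines > 0, line_period > 0, pixels_per_line >= 8,
            n_membranes >= 1, psf_sigma > 0, motion_amplitude >= 0,
            motion_tau > 0, noise_sd >= 0, baseline_offset >= 0)
  stopifnot(all(c("a", "b", "c", "d") %in% names(bleach)),
            bleach[["b"]] <= 0, bleach[["d"]] <= 0,
            bleach[["a"]] >= 0, bleach[["c"]] >= 0,
            bleach[["a"]] + bleach[["c"]] > 0)
  names(conditions) <- vapply(conditions, `[[`, "", "label")
  structure(list(conditions = conditions,
                 n_recordings = as.integer(n_recordings),
                 n_lines = as.integer(n_lines), line_period = line_period,
                 pixels_per_line = as.integer(pixels_per_line),
                 n_membranes = as.integer(n_membranes),
                 psf_sigma = psf_sigma, motion_amplitude = motion_amplitude,
                 motion_tau = motion_tau, bleach = bleach,
                 noise_sd = noise_sd, noise_model = noise_model,
                 baseline_offset = baseline_offset),
            class = "synth_config")
}

#' Default calibrated three-condition configuration
#'
#' The committed study conditions: control, propranolol (beta-blocker) and
#' isoproterenol (beta-agonist), with waveform counts 145/100/212 (32/22/46%
#' of 457). Effect directions follow the pharmacology of spontaneously
#' beating hiPS-derived cardiomyocytes: isoproterenol raises beat rate,
#' upslope, maximum height and plateau height and narrows the waveform;
#' propranolol lowers beat rate and widens the waveform. Effect sizes and
#' variances are calibration constants of the generator, fixed so that the
#' classes overlap realistically (no single metric separates them).
#'
#' @param n_waveforms Integer vector of per-condition waveform counts,
#'   named or ordered control, propranolol, isoproterenol.
#' @return A [synth_config()] object.
#' @export
default_synth_config <- function(n_waveforms = c(control = 145L,
                                                 propranolol = 100L,
                                                 isoproterenol = 212L)) {
  # calibration constants of the generator: treated cells carry more
  # pulse-shape variability than untreated controls
  sd_ctrl <- c(amplitude = 0.017, rise = 0.011, plateau = 0.041,
               fall = 0.032, plateau_end_frac = 0.034)
  sd_drug <- c(amplitude = 0.024, rise = 0.0156, plateau = 0.058,
               fall = 0.045, plateau_end_frac = 0.049)
  conds <- list(
    condition_config("control", beat_rate_mean = 70, beat_rate_sd = 6,
      pulse_mean = pulse_params(0.100, 0.080, 0.25, 0.20, 0.85),
      pulse_sd = sd_ctrl, variance_split = 0.2,
      n_waveforms = n_waveforms[[1]]),
    condition_config("propranolol", beat_rate_mean = 55, beat_rate_sd = 6,
      pulse_mean = pulse_params(0.095, 0.085, 0.36, 0.24, 0.84),
      pulse_sd = sd_drug, variance_split = 0.2,
      n_waveforms = n_waveforms[[2]]),
    condition_config("isoproterenol", beat_rate_mean = 95, beat_rate_sd = 8,
      pulse_mean = pulse_params(0.130, 0.060, 0.185, 0.162, 0.88),
      pulse_sd = sd_drug, variance_split = 0.2,
      n_waveforms = n_waveforms[[3]]))
  synth_config(conds, n_recordings = 16L)
}

#' Write / read a synthetic-study configuration as YAML
#'
#' @param config A [synth_config()] object.
#' @param path File path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a [synth_config()] object.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  x <- unclass(config)
  x$bleach <- as.list(x$bleach)
  x$conditions <- lapply(unname(config$conditions), function(cc) {
    list(label = cc$label, beat_rate_mean = cc$beat_rate_mean,
         beat_rate_sd = cc$beat_rate_sd,
         pulse_mean = unclass(cc$pulse_mean),
         pulse_sd = as.list(cc$pulse_sd),
         variance_split = cc$variance_split, n_waveforms = cc$n_waveforms)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  conds <- lapply(x$conditions, function(cc) {
    pm <- cc$pulse_mean
    condition_config(cc$label, cc$beat_rate_mean, cc$beat_rate_sd,
      pulse_params(pm$amplitude, pm$rise, pm$plateau, pm$fall,
                   pm$plateau_end_frac, pm$shape_sigma),
      unlist(cc$pulse_sd), cc$variance_split, cc$n_waveforms)
  })
  synth_config(conds, n_recordings = x$n_recordings, n_lines = x$n_lines,
               line_period = x$line_period,
               pixels_per_line = x$pixels_per_line,
               n_membranes = x$n_membranes, psf_sigma = x$psf_sigma,
               motion_amplitude = x$motion_amplitude,
               motion_tau = x$motion_tau, bleach = unlist(x$bleach),
               noise_sd = x$noise_sd, noise_model = x$noise_model,
               baseline_offset = x$baseline_offset)
}
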