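# Hierarchical draws of pulse parameters: cell-level shift + beat jitter.
# Strictly positive parameters are redrawn on non-positive values
# (truncation); the redraw count is accumulated in the environment `log`.
draw_pulse <- function(cond, cell_shift, log_env) {
  mu <- cond$pulse_mean
  sdb <- cond$pulse_sd * sqrt(1 - cond$variance_split)
  draw1 <- function(name, lower, upper = Inf) {
    m <- mu[[name]] + cell_shift[[name]]
    for (i in 1:100) {
      v <- rnorm(1, m, sdb[[name]])
      if (v > lower && v <= upper) return(v)
      log_env$n_redraws <- log_env$n_redraws + 1L
    }
    stop("parameter '", name, "' cannot be drawn in its support")
  }
  pulse_params(amplitude = draw1("amplitude", 0),
               rise = draw1("rise", 0),
               plateau = if (sdb[["plateau"]] > 0 || cell_shift[["plateau"]] != 0)
                 max(0, rnorm(1, mu$plateau + cell_shift[["plateau"]],
                              sdb[["plateau"]])) else mu$plateau,
               fall = draw1("fall", 0),
               plateau_end_frac = draw1("plateau_end_frac", 0.51, 1))
}

cell_shifts <- function(cond) {
  sdc <- cond$pulse_sd * sqrt(cond$variance_split)
  setNames(rnorm(length(sdc), 0, sdc), names(sdc))
}

# split n waveforms as evenly as possible over k recordings
split_counts <- function(n, k) {
  base <- diff(round(seq(0, n, length.out = k + 1)))
  as.integer(base[base > 0])
}

#' Simulate a per-waveform feature table directly from the pulse model
#'
#' Draws per-beat pulse parameters from the hierarchical condition model
#' (cell-level mean shift shared within a recording plus beat-level jitter),
#' converts each draw to the five waveform metrics via their closed forms,
#' and assembles a labelled feature table. This bypasses the imaging model
#' and is the fast path for classifier calibration and validation.
#'
#' @param config A [synth_config()] object.
#' @param seed Integer RNG seed; the output is reproducible given the seed.
#' @return A list with `features` (a `feature_table` data.frame with columns
#'   `h_max, m_up, m_down, w, h_plateau, label, recording_id, membrane_id,
#'   beat_time_s`) and `truth` (per-beat true pulse parameters). The number
#'   of truncation redraws is attached as attribute `n_redraws` on
#'   `features`.
#' @export
simulate_feature_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  log_env <- new.env(); log_env$n_redraws <- 0L
  rows <- list(); truth <- list()
  for (cond in config$conditions) {
    if (cond$n_waveforms <= 0) stop("zero waveform count for ", cond$label)
    per_rec <- split_counts(cond$n_waveforms, config$n_recordings)
    for (ri in seq_along(per_rec)) {
      rec_id <- sprintf("%s_r%d", cond$label, ri)
      shift <- cell_shifts(cond)
      rate <- max(10, rnorm(1, cond$beat_rate_mean, cond$beat_rate_sd))
      ibi <- 60 / rate
      bt <- cumsum(abs(rnorm(per_rec[ri], ibi, 0.05 * ibi)))
      for (bi in seq_len(per_rec[ri])) {
        pp <- draw_pulse(cond, shift, log_env)
        m <- pulse_metrics(pp)
        rows[[length(rows) + 1L]] <- data.frame(
          h_max = m$h_max, m_up = m$m_up, m_down = m$m_down, w = m$w,
          h_plateau = m$h_plateau, label = cond$label,
          recording_id = rec_id, membrane_id = "m1", beat_time_s = bt[bi],
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          label = cond$label, recording_id = rec_id, beat_time_s = bt[bi],
          amplitude = pp$amplitude, rise = pp$rise, plateau = pp$plateau,
          fall = pp$fall, plateau_end_frac = pp$plateau_end_frac,
          beat_rate = rate, stringsAsFactors = FALSE)
      }
    }
  }
  features <- do.call(rbind, rows)
  class(features) <- c("feature_table", "data.frame")
  attr(features, "n_redraws") <- log_env$n_redraws
  if (log_env$n_redraws > 0)
    message("simulate_feature_table: ", log_env$n_redraws,
            " out-of-support draws truncated (redrawn)")
  list(features = features, truth = do.call(rbind, truth))
}

# single-pole low-pass IIR, unit DC gain
lowpass <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
}

#' Simulate a line-scan recording (kymograph) for one condition
#'
#' Builds the full imaging model: each membrane contributes a Gaussian
#' profile of width `psf_sigma` whose centre follows beat-coupled motion
#' (the low-pass-filtered beat train scaled to `motion_amplitude` pixels)
#' and whose amplitude is `bleach(t) * (1 + V(t))` where `V(t)` is the
#' train of ΔF/F pulses; a constant background and noise are added.
#'
#' @param config A [synth_config()] object.
#' @param label Condition label; must name one of `config$conditions`.
#' @param seed Integer RNG seed.
#' @return List with `recording` (a [line_scan_recording()]) and `truth`
#'   (onset times, per-beat pulse parameters and closed-form metrics,
#'   per-line membrane centres, condition label).
#' @export
simulate_recording <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cond <- config$conditions[[label]]
  if (is.null(cond)) stop("unknown condition label: ", label)
  if (!is.null(seed)) set.seed(seed)
  log_env <- new.env(); log_env$n_redraws <- 0L
  n <- config$n_lines; npx <- config$pixels_per_line
  t <- (seq_len(n) - 1L) * config$line_period
  dur <- n * config$line_period

  # membrane base positions, evenly spread over the central 60% of the line
  mu0 <- seq(0.2, 0.8, length.out = config$n_membranes + 2L)[
    seq_len(config$n_membranes) + 1L] * (npx - 1)
  if (config$n_membranes > 1 && min(diff(mu0)) < 4 * config$psf_sigma)
    warning("unresolvable membranes: separation < 4 * psf_sigma")

  # shared beat train (cluster beats synchronously)
  rate <- max(10, rnorm(1, cond$beat_rate_mean, cond$beat_rate_sd))
  ibi <- 60 / rate
  onsets <- c(); tt <- abs(rnorm(1, 0.5 * ibi, 0.05 * ibi))
  while (tt < dur) {
    onsets <- c(onsets, tt)
    tt <- tt + abs(rnorm(1, ibi, 0.05 * ibi))
  }
  shift <- cell_shifts(cond)
  beat_pp <- lapply(seq_along(onsets), function(i)
    draw_pulse(cond, shift, log_env))
  v <- numeric(n)
  for (i in seq_along(onsets)) {
    pp <- beat_pp[[i]]
    span <- pp$rise + pp$plateau + pp$fall
    idx <- which(t >= onsets[i] & t <= onsets[i] + span)
    if (length(idx)) v[idx] <- v[idx] + pulse_value(pp, t[idx] - onsets[i])
  }

  motion <- lowpass(v, config$line_period, config$motion_tau)
  if (config$motion_amplitude > 0 && max(abs(motion)) > 0)
    motion <- motion / max(abs(motion)) * config$motion_amplitude
  else motion <- motion * 0
  centers <- outer(motion, mu0, `+`)
  if (any(centers < 0) || any(centers > npx - 1))
    stop("membrane motion pushes a centre out of frame")

  bl <- config$bleach
  bleach_t <- bl[["a"]] * exp(bl[["b"]] * t) + bl[["c"]] * exp(bl[["d"]] * t)
  px <- seq_len(npx) - 1L
  mat <- matrix(config$baseline_offset, n, npx)
  mem_scale <- seq(1, 0.8, length.out = config$n_membranes)
  for (m in seq_len(config$n_membranes)) {
    amp <- mem_scale[m] * bleach_t * (1 + v)
    prof <- exp(-(outer(centers[, m], px, `-`))^2 / (2 * config$psf_sigma^2))
    mat <- mat + amp * prof
  }
  if (config$noise_model == "poisson") {
    mat <- matrix(rpois(length(mat), pmax(mat, 0)), n, npx)
  } else if (config$noise_sd > 0) {
    mat <- mat + rnorm(length(mat), 0, config$noise_sd)
  }
  mat[mat < 0] <- 0

  metrics <- do.call(rbind, lapply(beat_pp, function(pp)
    as.data.frame(pulse_metrics(pp)[c("h_max", "m_up", "m_down", "w",
                                      "h_plateau")])))
  truth <- list(label = label, onsets = onsets, pulse_params = beat_pp,
                metrics = metrics, centers = centers, beat_rate = rate,
                bleach = bl, motion = motion,
                n_redraws = log_env$n_redraws)
  rec <- line_scan_recording(mat, config$line_period,
                             metadata = list(label = label))
  list(recording = rec, truth = truth)
}

#' Write / read a line-scan recording as 16-bit TIFF plus YAML sidecar
#'
#' The intensity matrix (lines x pixels) is stored as a single-page 16-bit
#' grayscale TIFF; line period and metadata go to `<path>.yml`.
#'
#' @param rec A [line_scan_recording()].
#' @param path TIFF file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [line_scan_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "line_scan_recording"))
  m <- round(rec$intensity)
  if (any(m > 65535)) {
    warning("intensities above 65535 clipped on write")
    m[m > 65535] <- 65535
  }
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  yaml::write_yaml(c(list(line_period = rec$line_period,
                          pixel_size = rec$pixel_size), rec$metadata),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- tiff::readTIFF(path) * 65535
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  line_scan_recording(round(m), line_period = meta$line_period,
                      pixel_size = meta$pixel_size,
                      metadata = meta[setdiff(names(meta),
                                              c("line_period", "pixel_size"))])
}
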