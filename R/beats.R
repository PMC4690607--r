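#' Segment a normalized trace into beats
#'
#' Peaks are local maxima with prominence at least `min_prominence`
#' (default: 4x the baseline noise sd, taken from the `noise_sd` attribute
#' set by [smooth_trace()], or estimated as `mad(diff(x))/sqrt(2)` when
#' absent) and mutual separation at least `min_separation` seconds. The
#' trough flanking each peak is the minimum of the trace between it and the
#' neighbouring peak; the trace ends bound the outer troughs. The beat rate
#' is `60 / median(inter-peak interval)`; with fewer than two peaks it is
#' reported as 0 with attribute `rate_undefined`.
#'
#' @param trace A smoothed `normalized_trace` data.frame (or numeric vector
#'   with `time_s` supplied).
#' @param min_prominence Minimum peak prominence (ΔF/F); see above.
#' @param min_separation Minimum peak separation (s; default 0.2).
#' @param time_s Time grid when `trace` is a bare vector.
#' @return An object of class `beat_set`: list with `segments` (data.frame
#'   of peak/trough indices, times and values), `beat_rate` (beats/min) and
#'   `n_beats`. An empty segment set is valid.
#' @export
detect_beats <- function(trace, min_prominence = NULL, min_separation = 0.2,
                         time_s = NULL) {
  if (is.data.frame(trace)) {
    x <- trace$value; t <- trace$time_s
  } else {
    x <- as.numeric(trace); t <- time_s
  }
  if (is.null(t)) stop("time_s required for a bare numeric trace")
  dt <- median(diff(t))
  if (is.null(min_prominence)) {
    ns <- attr(trace, "noise_sd")
    if (is.null(ns)) ns <- mad(diff(x)) / sqrt(2)
    min_prominence <- 4 * ns
  }
  sep <- max(1L, as.integer(ceiling(min_separation / dt)))
  pk <- find_peaks(x, min_prominence = min_prominence, min_separation = sep)
  if (!length(pk)) {
    out <- list(segments = data.frame(), beat_rate = 0, n_beats = 0L)
    class(out) <- "beat_set"
    attr(out, "rate_undefined") <- TRUE
    return(out)
  }
  n <- length(x)
  bounds <- c(1L, pk, n)
  tb <- integer(length(pk)); ta <- integer(length(pk))
  for (i in seq_along(pk)) {
    lspan <- bounds[i]:pk[i]
    tb[i] <- lspan[which.min(x[lspan])]
    rspan <- pk[i]:bounds[i + 2L]
    ta[i] <- rspan[which.min(x[rspan])]
  }
  seg <- data.frame(peak_idx = pk, peak_time = t[pk], peak_value = x[pk],
                    trough_before_idx = tb, trough_before_time = t[tb],
                    trough_before_value = x[tb],
                    trough_after_idx = ta, trough_after_time = t[ta],
                    trough_after_value = x[ta])
  rate <- if (length(pk) >= 2L) 60 / median(diff(t[pk])) else 0
  out <- list(segments = seg, beat_rate = rate, n_beats = length(pk))
  class(out) <- "beat_set"
  if (length(pk) < 2L) attr(out, "rate_undefined") <- TRUE
  out
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("beat_set: %d beats, rate %.1f beats/min%s\n", x$n_beats,
              x$beat_rate,
              if (isTRUE(attr(x, "rate_undefined"))) " (rate undefined)"
              else ""))
  invisible(x)
}

# half-maximum crossing nearest the peak on one limb.
# side = -1 rising (scan leftwards), +1 falling (scan rightwards).
half_crossing <- function(x, t, peak, bound, level, side) {
  i <- peak
  while (i != bound && x[i + side] >= level) i <- i + side
  if (i == bound && x[i] >= level) return(NULL)     # no crossing on limb
  j <- i + side                                     # x[j] < level <= x[i]
  lo <- min(i, j); hi <- max(i, j)
  tc <- t[lo] + (level - x[lo]) / (x[hi] - x[lo]) * (t[hi] - t[lo])
  slope <- (x[hi] - x[lo]) / (t[hi] - t[lo])
  list(t = tc, slope = slope)
}

#' Compute the five waveform metrics for each beat
#'
#' For every segment: baseline = mean of the two flanking trough values;
#' `h_max` = peak minus baseline; the half-maximum level is baseline +
#' `h_max`/2; `t_up` / `t_down` are the linearly interpolated crossings of
#' that level nearest the peak on the rising / falling limb; `m_up` /
#' `m_down` are the finite-difference slopes across the samples bracketing
#' each crossing; `w = t_down - t_up`; `h_plateau` is the interpolated
#' trace value at the width midpoint minus baseline. Beats lacking a
#' half-maximum crossing on either limb are rejected with a reason and
#' reported in the QC component.
#'
#' @param beats A `beat_set` from [detect_beats()].
#' @param trace The same trace the beats were detected on.
#' @param time_s Time grid when `trace` is a bare vector.
#' @return List with `metrics` (data.frame `beat_time, h_max, m_up, m_down,
#'   w, h_plateau`) and `rejected` (data.frame `beat_time, reason`).
#' @export
compute_metrics <- function(beats, trace, time_s = NULL) {
  stopifnot(inherits(beats, "beat_set"))
  if (is.data.frame(trace)) {
    x <- trace$value; t <- trace$time_s
  } else {
    x <- as.numeric(trace); t <- time_s
  }
  rows <- list(); rej <- list()
  seg <- beats$segments
  for (k in seq_len(nrow(seg))) {
    s <- seg[k, ]
    baseline <- mean(c(s$trough_before_value, s$trough_after_value))
    h_max <- s$peak_value - baseline
    if (h_max <= 0) {
      rej[[length(rej) + 1L]] <- data.frame(beat_time = s$peak_time,
                                            reason = "non-positive height")
      next
    }
    level <- baseline + h_max / 2
    up <- half_crossing(x, t, s$peak_idx, s$trough_before_idx, level, -1L)
    dn <- half_crossing(x, t, s$peak_idx, s$trough_after_idx, level, +1L)
    if (is.null(up) || is.null(dn)) {
      rej[[length(rej) + 1L]] <- data.frame(
        beat_time = s$peak_time,
        reason = if (is.null(up)) "no rising half-maximum crossing"
                 else "no falling half-maximum crossing")
      next
    }
    t_mid <- (up$t + dn$t) / 2
    h_plateau <- approx(t, x, xout = t_mid)$y - baseline
    rows[[length(rows) + 1L]] <- data.frame(
      beat_time = s$peak_time, h_max = h_max, m_up = up$slope,
      m_down = dn$slope, w = dn$t - up$t, h_plateau = h_plateau)
  }
  list(metrics = if (length(rows)) do.call(rbind, rows) else
         data.frame(beat_time = numeric(), h_max = numeric(),
                    m_up = numeric(), m_down = numeric(), w = numeric(),
                    h_plateau = numeric()),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(beat_time = numeric(), reason = character()))
}

#' Assemble a labelled feature table from per-recording metrics
#'
#' @param metrics_list List of metric data.frames (from
#'   [compute_metrics()]`$metrics`), one per recording/membrane.
#' @param labels Character vector of condition labels, one per element of
#'   `metrics_list`.
#' @param recording_ids Character vector of recording IDs, same length.
#' @param membrane_ids Optional membrane IDs (default "m1").
#' @return A `feature_table` data.frame ordered by (recording, membrane,
#'   beat time) with columns `h_max, m_up, m_down, w, h_plateau, label,
#'   recording_id, membrane_id, beat_time_s`.
#' @export
build_feature_table <- function(metrics_list, labels, recording_ids,
                                membrane_ids = NULL) {
  stopifnot(length(metrics_list) >= 1,
            length(labels) == length(metrics_list),
            length(recording_ids) == length(metrics_list))
  if (any(is.na(labels) | !nzchar(labels)))
    stop("missing condition label for a recording")
  if (is.null(membrane_ids)) membrane_ids <- rep("m1", length(labels))
  parts <- lapply(seq_along(metrics_list), function(i) {
    m <- metrics_list[[i]]
    if (!nrow(m)) return(NULL)
    data.frame(h_max = m$h_max, m_up = m$m_up, m_down = m$m_down, w = m$w,
               h_plateau = m$h_plateau, label = labels[i],
               recording_id = recording_ids[i],
               membrane_id = membrane_ids[i], beat_time_s = m$beat_time,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("no waveforms in any input")
  out <- out[order(out$recording_id, out$membrane_id, out$beat_time_s), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

metric_names <- c("h_max", "m_up", "m_down", "w", "h_plateau")
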