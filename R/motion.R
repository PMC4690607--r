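#' Line-scan recording container
#'
#' A kymograph: one row per line scan (time step), one column per pixel.
#' Pixel coordinates used throughout the package are 0-based, i.e. column
#' `j` of the matrix sits at position `j - 1` px, so membrane centres live
#' in `[0, n_pixels)`.
#'
#' @param intensity Numeric matrix, `n_lines x n_pixels`, non-negative.
#' @param line_period Seconds per line.
#' @param pixel_size Optional physical pixel size (arbitrary units).
#' @param metadata Named list (condition label, recording ID, ...).
#' @return An object of class `line_scan_recording`.
#' @export
line_scan_recording <- function(intensity, line_period, pixel_size = NULL,
                                metadata = list()) {
  stopifnot(is.matrix(intensity), nrow(intensity) >= 2,
            ncol(intensity) >= 8, all(intensity >= 0), line_period > 0)
  structure(list(intensity = intensity, line_period = line_period,
                 pixel_size = pixel_size, metadata = metadata),
            class = "line_scan_recording")
}

#' @export
print.line_scan_recording <- function(x, ...) {
  cat(sprintf("line_scan_recording: %d lines x %d px, %.6g s/line (%.3g s)\n",
              nrow(x$intensity), ncol(x$intensity), x$line_period,
              nrow(x$intensity) * x$line_period))
  if (!is.null(x$metadata$label)) cat("  label:", x$metadata$label, "\n")
  invisible(x)
}

#' Prominence-based local-maximum detection
#'
#' The prominence of a candidate peak is its height above the higher of the
#' two deepest valleys separating it from the nearest greater values on
#' either side (series ends count as bounds). Peaks are kept if their
#' prominence reaches `min_prominence`; when two surviving peaks are closer
#' than `min_separation` samples the smaller is dropped.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence.
#' @param min_separation Minimum index distance between kept peaks.
#' @return Integer vector of peak indices, ascending.
#' @export
find_peaks <- function(x, min_prominence, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # drop all but the first sample of flat-topped runs
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, diff(cand) > 1L | diff(x[cand]) != 0)]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lhs <- which(x[seq_len(i - 1L)] > x[i])
    lo_l <- min(x[(if (length(lhs)) max(lhs) else 1L):i])
    rhs <- which(x[(i + 1L):n] > x[i])
    hi <- if (length(rhs)) i + min(rhs) else n
    lo_r <- min(x[i:hi])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) > 1L && min_separation > 1L) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- integer(0)
    for (i in ord)
      if (!length(sel) || min(abs(sel - i)) >= min_separation)
        sel <- c(sel, i)
    keep <- sort(sel)
  }
  keep
}

#' Locate membranes in the time-averaged line profile
#'
#' @param recording A [line_scan_recording()].
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   profile range (default 0.2).
#' @param min_separation_px Minimum separation between membranes (px).
#' @details A peak must clear both the relative prominence threshold and a
#'   noise floor of 6 standard errors of the time-averaged profile
#'   (estimated from the per-pixel line-to-line scatter), so a recording of
#'   pure noise yields "no membranes found" rather than a spurious centre.
#' @return Numeric vector of initial membrane centres (0-based px),
#'   ascending.
#' @export
detect_membranes <- function(recording, prominence_frac = 0.2,
                             min_separation_px = 4) {
  stopifnot(inherits(recording, "line_scan_recording"))
  mat <- recording$intensity
  prof <- colMeans(mat)
  rng <- diff(range(prof))
  noise_se <- median(apply(mat, 2, sd)) / sqrt(nrow(mat))
  if (rng <= 0) stop("no membranes found")
  pk <- find_peaks(prof,
                   min_prominence = max(prominence_frac * rng,
                                        6 * noise_se),
                   min_separation = as.integer(min_separation_px))
  if (!length(pk)) stop("no membranes found")
  pk - 1  # 0-based pixel coordinates
}

# Gaussian + offset fit on a pixel window; returns NULL on failure
fit_gauss_line <- function(px, y, start) {
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ F * exp(-(px - mu)^2 / (2 * sigma^2)) + off,
    start = start,
    lower = c(F = 0, mu = min(px), sigma = 0.3, off = 0),
    upper = c(F = Inf, mu = max(px), sigma = diff(range(px)), off = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 60))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(coef(fit))
}

#' Track one membrane across all line scans
#'
#' For each line a Gaussian `F * exp(-(x - mu)^2 / (2 sigma^2)) + offset`
#' is least-squares fitted within `search_halfwidth` pixels of the previous
#' line's accepted centre (causal tracking). The corrected intensity is the
#' fitted amplitude `F` (background excluded), which is invariant to the
#' membrane's width and position. Lines whose fit fails, whose centre jumps
#' by more than `search_halfwidth`, or whose amplitude is non-positive are
#' flagged and filled by linear interpolation of centre, width and
#' amplitude.
#'
#' @param recording A [line_scan_recording()].
#' @param init_center Initial centre (0-based px), e.g. from
#'   [detect_membranes()].
#' @param search_halfwidth Fit window half-width in px (>= 2, default 6).
#' @param membrane_id Identifier carried into the output.
#' @param mode `"amplitude"` (default, corrected intensity = fitted Gaussian
#'   amplitude) or `"windowed_sum"` (background-subtracted sum over the fit
#'   window).
#' @return A `membrane_trace` data.frame with columns `line`, `time_s`,
#'   `center_px`, `sigma_px`, `intensity`, `flag`.
#' @export
track_membrane <- function(recording, init_center, search_halfwidth = 6,
                           membrane_id = "m1",
                           mode = c("amplitude", "windowed_sum")) {
  stopifnot(inherits(recording, "line_scan_recording"),
            search_halfwidth >= 2)
  mode <- match.arg(mode)
  mat <- recording$intensity
  n <- nrow(mat); npx <- ncol(mat)
  if (init_center < 0 || init_center > npx - 1)
    stop("init_center outside the frame")
  hw <- search_halfwidth
  center <- numeric(n); sigma <- numeric(n); amp <- numeric(n)
  flag <- logical(n)
  prev <- list(mu = init_center, sigma = 2, F = NA_real_, off = NA_real_)
  for (i in seq_len(n)) {
    lo <- max(1L, floor(prev$mu) + 1L - hw)
    hi <- min(npx, ceiling(prev$mu) + 1L + hw)
    px <- (lo:hi) - 1
    y <- mat[i, lo:hi]
    st <- list(F = if (is.na(prev$F)) max(y) - min(y) else prev$F,
               mu = prev$mu, sigma = prev$sigma,
               off = if (is.na(prev$off)) min(y) else prev$off)
    st$F <- max(st$F, 1e-6); st$sigma <- min(max(st$sigma, 0.5), hw)
    cf <- fit_gauss_line(px, y, st)
    ok <- !is.null(cf) && is.finite(cf$mu) && cf$F > 0 &&
      abs(cf$mu - prev$mu) <= hw
    if (ok) {
      center[i] <- cf$mu; sigma[i] <- cf$sigma
      amp[i] <- if (mode == "amplitude") cf$F else sum(pmax(y - cf$off, 0))
      prev <- cf
    } else {
      flag[i] <- TRUE
      center[i] <- NA_real_; sigma[i] <- NA_real_; amp[i] <- NA_real_
    }
  }
  if (mean(flag) > 0.2)
    stop("tracking unreliable for membrane ", membrane_id, ": ",
         round(100 * mean(flag)), "% of lines failed to fit")
  if (any(flag)) {
    good <- which(!flag)
    interp <- function(v) approx(good, v[good], xout = seq_len(n),
                                 rule = 2)$y
    center <- interp(center); sigma <- interp(sigma); amp <- interp(amp)
  }
  out <- data.frame(line = seq_len(n),
                    time_s = (seq_len(n) - 1L) * recording$line_period,
                    center_px = center, sigma_px = sigma,
                    intensity = pmax(amp, 0), flag = flag)
  class(out) <- c("membrane_trace", "data.frame")
  attr(out, "membrane_id") <- membrane_id
  attr(out, "mode") <- mode
  out
}

#' Write / read a membrane trace as CSV
#'
#' @param trace A `membrane_trace` data.frame.
#' @param path CSV path.
#' @return `write_membrane_trace` returns `path` invisibly;
#'   `read_membrane_trace` returns a `membrane_trace`.
#' @export
write_membrane_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membrane_trace
#' @export
read_membrane_trace <- function(path) {
  out <- read.csv(path)
  class(out) <- c("membrane_trace", "data.frame")
  out
}
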