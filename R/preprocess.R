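# log-linear seeding of a single exponential a*exp(b*t) on (t, y), y > 0
loglin_seed <- function(t, y) {
  y <- pmax(y, 1e-9)
  cf <- coef(stats::lm(log(y) ~ t))
  c(a = unname(exp(cf[1])), b = min(unname(cf[2]), 0))
}

#' Photobleaching correction by double-exponential detrending
#'
#' Fits the photobleaching model `F(t) = a*exp(b*t) + c*exp(d*t)` (with
#' exponents constrained <= 0) to the full intensity trace by
#' Levenberg-Marquardt least squares, then returns the normalized trace
#' `(F - fit) / fit`, i.e. ΔF/F relative to the time-varying bleach
#' estimate. Seeding is two-timescale: a log-linear fit to the last third
#' of the trace seeds the slow component `(c, d)`, a log-linear fit to the
#' residual over the first third seeds the fast component `(a, b)`. If the
#' double-exponential fit does not converge the function falls back to a
#' single exponential, and failing that to the trace mean; the fallback is
#' recorded and messaged.
#'
#' @param trace A `membrane_trace` (from [track_membrane()]) or numeric
#'   intensity vector.
#' @param time_s Time grid (s); taken from the trace when omitted.
#' @param mask_beats If `TRUE`, refit after excluding samples that sit on
#'   beat crests (positive residuals beyond 2 robust sds of the first
#'   pass), removing the small upward bias the beats impose on the bleach
#'   estimate. Default `FALSE`: the model is fitted to the full trace,
#'   beats included, and the bias is bounded by the beat duty cycle.
#' @return List with `fit` (class `bleach_fit`: `a`, `b`, `c`, `d`,
#'   `fitted`, `sse`, `fallback`) and `trace` (class `normalized_trace`,
#'   a data.frame with `time_s` and ΔF/F `value`).
#' @export
correct_photobleach <- function(trace, time_s = NULL, mask_beats = FALSE) {
  if (mask_beats) {
    first <- correct_photobleach(trace, time_s, mask_beats = FALSE)
    r <- first$trace$value
    keep <- r < 2 * mad(r)
    if (sum(keep) >= 100) {
      y0 <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
      t0 <- if (is.data.frame(trace)) trace$time_s else time_s
      sub <- correct_photobleach(y0[keep], t0[keep], mask_beats = FALSE)
      fit_vals <- with(sub$fit, a * exp(b * t0) + c * exp(d * t0))
      if (all(fit_vals > 0)) {
        norm <- data.frame(time_s = t0, value = (y0 - fit_vals) / fit_vals)
        class(norm) <- c("normalized_trace", "data.frame")
        sub$fit$fitted <- fit_vals
        sub$fit$sse <- sum((y0 - fit_vals)^2)
        return(list(fit = sub$fit, trace = norm))
      }
    }
    return(first)
  }
  correct_photobleach_impl(trace, time_s)
}

correct_photobleach_impl <- function(trace, time_s = NULL) {
  if (inherits(trace, "membrane_trace") || is.data.frame(trace)) {
    y <- trace$intensity
    t <- trace$time_s
  } else {
    y <- as.numeric(trace)
    t <- time_s
  }
  if (is.null(t)) stop("time_s required for a bare numeric trace")
  if (length(y) < 100) stop("trace too short: need at least 100 lines")
  if (any(!is.finite(y)) || any(y <= 0))
    stop("intensities must be finite and strictly positive")

  fallback <- "none"
  n <- length(y)
  # fit on a unit-mean trace so convergence (and hence the normalized
  # output) is exactly invariant to the overall intensity scale
  y_scale <- mean(y)
  y <- y / y_scale
  fit_vals <- NULL; ab <- NULL
  if (sd(y) > 1e-12 * mean(y)) {
    i1 <- seq_len(ceiling(n / 3))
    i3 <- seq.int(floor(2 * n / 3), n)
    slow <- loglin_seed(t[i3], y[i3])
    resid1 <- y[i1] - slow[["a"]] * exp(slow[["b"]] * t[i1])
    fast <- if (any(resid1 > 0)) {
      pos <- resid1 > 0
      loglin_seed(t[i1][pos], resid1[pos])
    } else c(a = 0.1 * slow[["a"]], b = -10 * abs(slow[["b"]]) - 1e-3)
    dfit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ a * exp(b * tt) + c * exp(d * tt),
      data = list(y = y, tt = t),
      start = list(a = fast[["a"]], b = min(fast[["b"]], -1e-6),
                   c = slow[["a"]], d = min(slow[["b"]], 0)),
      lower = c(a = 0, b = -Inf, c = 0, d = -Inf),
      upper = c(a = Inf, b = 0, c = Inf, d = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (!inherits(dfit, "try-error")) {
      ab <- as.list(coef(dfit))
      fit_vals <- predict(dfit)
    } else {
      sfit <- try(suppressWarnings(minpack.lm::nlsLM(
        y ~ a * exp(b * tt), data = list(y = y, tt = t),
        start = list(a = slow[["a"]], b = slow[["b"]]),
        lower = c(a = 0, b = -Inf), upper = c(a = Inf, b = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
        silent = TRUE)
      if (!inherits(sfit, "try-error")) {
        fallback <- "single_exponential"
        cf <- coef(sfit)
        ab <- list(a = cf[["a"]], b = cf[["b"]], c = 0, d = 0)
        fit_vals <- predict(sfit)
      }
    }
  }
  if (is.null(fit_vals)) {
    fallback <- if (sd(y) > 1e-12 * mean(y)) "constant" else "constant"
    ab <- list(a = mean(y), b = 0, c = 0, d = 0)
    fit_vals <- rep(mean(y), n)
  }
  if (fallback != "none")
    message("correct_photobleach: fell back to ", fallback, " model")
  if (any(fit_vals <= 0)) stop("invalid bleach model: fit is not positive")
  ab$a <- ab$a * y_scale
  ab$c <- ab$c * y_scale
  fit_vals <- fit_vals * y_scale
  y <- y * y_scale

  norm <- data.frame(time_s = t, value = (y - fit_vals) / fit_vals)
  class(norm) <- c("normalized_trace", "data.frame")
  fit <- structure(list(a = ab$a, b = ab$b, c = ab$c, d = ab$d,
                        fitted = fit_vals,
                        sse = sum((y - fit_vals)^2), fallback = fallback),
                   class = "bleach_fit")
  list(fit = fit, trace = norm)
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("bleach_fit: %.4g*exp(%.4g t) + %.4g*exp(%.4g t), SSE=%.4g%s\n",
              x$a, x$b, x$c, x$d, x$sse,
              if (x$fallback != "none") paste0(" [fallback: ", x$fallback,
                                               "]") else ""))
  invisible(x)
}

#' Moving-average smoothing of a normalized trace
#'
#' Centred moving average over `window` lines (an even window is centred
#' with one extra sample on the left, so the interior impulse response of a
#' 50-line window is a 50-sample boxcar of height 1/50). At the edges the
#' window shrinks to the available samples; no padding values are invented.
#' The median absolute deviation of the smoothing residual is attached as
#' attribute `noise_sd` for downstream peak-detection thresholds.
#'
#' @param trace A `normalized_trace` data.frame or numeric vector.
#' @param window Window length in lines (>= 1, < trace length; default 50).
#' @return Same shape as the input, smoothed; attribute `window` and
#'   `noise_sd` attached.
#' @export
smooth_trace <- function(trace, window = 50) {
  is_df <- is.data.frame(trace)
  x <- if (is_df) trace$value else as.numeric(trace)
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window >= n) stop("window must be smaller than the trace length")
  left <- window %/% 2L
  right <- window - 1L - left
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  noise_sd <- mad(x - out)
  if (is_df) {
    res <- trace
    res$value <- out
  } else res <- out
  attr(res, "window") <- window
  attr(res, "noise_sd") <- noise_sd
  res
}
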