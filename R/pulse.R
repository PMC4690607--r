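#' Parameters of a phenomenological action-potential pulse
#'
#' The depolarization waveform of one beat is modelled as a trapezoid with a
#' sagging plateau: a linear rise from 0 to `amplitude` over `rise` seconds,
#' a linear sag from `amplitude` down to `plateau_end_frac * amplitude` over
#' `plateau` seconds, and a linear fall back to 0 over `fall` seconds. An
#' optional Gaussian smoothing of width `shape_sigma` rounds the corners.
#' With `shape_sigma = 0` the five waveform metrics (see
#' [pulse_metrics()]) have closed forms, which makes the pulse usable as an
#' exact oracle for the measurement pipeline.
#'
#' @param amplitude Peak height A (ΔF/F, dimensionless), > 0.
#' @param rise Rise duration r (s), > 0.
#' @param plateau Plateau (sag) duration d (s), >= 0.
#' @param fall Fall duration f (s), > 0.
#' @param plateau_end_frac Fraction p of the amplitude remaining at the end
#'   of the plateau, in (0, 1].
#' @param shape_sigma Gaussian smoothing width (s), >= 0.
#' @return An object of class `pulse_params`.
#' @export
pulse_params <- function(amplitude, rise, plateau, fall,
                         plateau_end_frac = 1, shape_sigma = 0) {
  stopifnot(amplitude > 0, rise > 0, fall > 0, plateau >= 0,
            plateau_end_frac > 0, plateau_end_frac <= 1, shape_sigma >= 0)
  structure(list(amplitude = amplitude, rise = rise, plateau = plateau,
                 fall = fall, plateau_end_frac = plateau_end_frac,
                 shape_sigma = shape_sigma),
            class = "pulse_params")
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf(
    "pulse_params: A=%.4g dF/F, rise=%.4g s, plateau=%.4g s, fall=%.4g s, p=%.3g, sigma=%.3g s\n",
    x$amplitude, x$rise, x$plateau, x$fall, x$plateau_end_frac,
    x$shape_sigma))
  invisible(x)
}

# piecewise trapezoid value at times t (no smoothing), vectorized
pulse_value <- function(params, t) {
  A <- params$amplitude; r <- params$rise; d <- params$plateau
  f <- params$fall; p <- params$plateau_end_frac
  y <- numeric(length(t))
  i <- t >= 0 & t < r
  y[i] <- A * t[i] / r
  if (d > 0) {
    i <- t >= r & t < r + d
    y[i] <- A * (1 - (1 - p) * (t[i] - r) / d)
  }
  i <- t >= r + d & t <= r + d + f
  y[i] <- p * A * (1 - (t[i] - r - d) / f)
  y
}

#' Evaluate a pulse on a time grid
#'
#' @param params A [pulse_params()] object.
#' @param t Uniform time grid (s) covering at least `[0, rise+plateau+fall]`.
#' @return Numeric vector of ΔF/F amplitudes, same length as `t`.
#' @export
make_ap_pulse <- function(params, t) {
  stopifnot(inherits(params, "pulse_params"), length(t) >= 3)
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt[1]), 1e-12))
    stop("time grid must be uniform")
  if (params$plateau == 0 && params$plateau_end_frac < 0.5)
    stop("degenerate pulse: 50% crossing on the fall limb is undefined ",
         "(plateau_end_frac < 0.5 with zero plateau duration)")
  y <- pulse_value(params, t)
  s <- params$shape_sigma
  if (s > 0) {
    h <- max(1L, ceiling(4 * s / dt[1]))
    k <- dnorm(seq(-h, h) * dt[1], sd = s)
    k <- k / sum(k)
    ypad <- c(numeric(h), y, numeric(h))
    y <- as.numeric(stats::filter(ypad, k, sides = 2))[(h + 1):(h + length(t))]
  }
  y
}

#' Closed-form waveform metrics of an unsmoothed pulse
#'
#' For `shape_sigma = 0` the five metrics of the measurement pipeline have
#' exact closed forms on the trapezoid-with-sag pulse (baseline 0):
#' `h_max = A`; the half-maximum level is A/2; `t_up = rise/2` and
#' `m_up = A/rise` on the rising limb; for `p > 1/2` the falling-limb
#' crossing lies on the final fall (`m_down = -pA/fall`), for `p <= 1/2` it
#' lies on the sag (`m_down = -(1-p)A/plateau`); `w = t_down - t_up`; and
#' `h_plateau` is the pulse value at the midpoint of the width.
#'
#' @param params A [pulse_params()] object with `shape_sigma = 0`.
#' @return Named list with `h_max`, `m_up`, `m_down`, `w`, `h_plateau`,
#'   `t_up`, `t_down`.
#' @export
pulse_metrics <- function(params) {
  stopifnot(inherits(params, "pulse_params"))
  if (params$shape_sigma != 0)
    stop("closed-form metrics require shape_sigma = 0")
  A <- params$amplitude; r <- params$rise; d <- params$plateau
  f <- params$fall; p <- params$plateau_end_frac
  if (d == 0 && p < 0.5)
    stop("degenerate pulse: 50% crossing on the fall limb is undefined")
  t_up <- r / 2
  if (p > 0.5) {
    t_down <- r + d + f * (p - 0.5) / p
    m_down <- -p * A / f
  } else {
    t_down <- r + 0.5 * d / (1 - p)
    m_down <- -(1 - p) * A / d
  }
  t_mid <- (t_up + t_down) / 2
  list(h_max = A, m_up = A / r, m_down = m_down, w = t_down - t_up,
       h_plateau = pulse_value(params, t_mid), t_up = t_up, t_down = t_down)
}
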