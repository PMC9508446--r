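#' Default tumbling-survival anchors
#'
#' The three digitized survival fractions from the abrasive-tumbling
#' experiments: 50% of spores remain viable after 1 minute, 3% after 1 hour,
#' 0.5% after 1 day of tumbling (one tumbling rotation per second).
#'
#' @return A tibble with columns `time_s` and `fraction`, time-sorted with
#'   non-increasing fractions.
#' @export
default_anchors <- function() {
  tibble::tibble(
    time_s = c(60, 3600, 86400),
    fraction = c(0.50, 0.03, 0.005)
  )
}

#' Spore-survival curve
#'
#' A survival model S(t) for spores under abrasive tumbling, either an
#' interpolant through measured anchors or a parametric Weibull.
#'
#' The interpolant is piecewise linear in (log time, log fraction), exact at
#' every anchor; it reflects that the digitized anchors are close to a power
#' law and that the underlying argument is made in orders of magnitude. The
#' Weibull form is \eqn{S(t) = \exp(-(t/\lambda)^k)}; shape `k < 1` gives
#' sub-exponential inactivation, i.e. the surviving population's half-life
#' keeps lengthening - the regime the tumbling data show.
#'
#' @param anchors Data frame with columns `time_s` (increasing, > 0) and
#'   `fraction` (in (0, 1], non-increasing). Required for
#'   `model = "interpolant"`; defaults to [default_anchors()].
#' @param model `"interpolant"` or `"weibull"`.
#' @param shape,scale Weibull parameters `k` (dimensionless) and `lambda`
#'   (seconds); required for `model = "weibull"`.
#' @return An object of class `survival_curve`.
#' @examples
#' curve <- survival_curve()
#' surviving_fraction(curve, 3600)  # 0.03
#' @export
survival_curve <- function(anchors = default_anchors(),
                           model = c("interpolant", "weibull"),
                           shape = NULL, scale = NULL) {
  model <- match.arg(model)
  if (model == "weibull") {
    if (is.null(shape) || is.null(scale) ||
        !is.finite(shape) || !is.finite(scale) || shape <= 0 || scale <= 0) {
      abort_marsalt("weibull model requires positive shape and scale",
                    "marsalt_invalid_curve")
    }
    return(structure(list(model = "weibull", shape = shape, scale = scale),
                     class = "survival_curve"))
  }
  if (!is.data.frame(anchors) ||
      !all(c("time_s", "fraction") %in% names(anchors)) ||
      nrow(anchors) < 2L) {
    abort_marsalt("anchors must be a data frame with >= 2 rows of time_s, fraction",
                  "marsalt_invalid_curve")
  }
  t <- anchors$time_s
  f <- anchors$fraction
  if (any(!is.finite(t)) || any(t <= 0) || any(diff(t) <= 0)) {
    abort_marsalt("anchor times must be positive and strictly increasing",
                  "marsalt_invalid_curve")
  }
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1) || any(diff(f) > 0)) {
    abort_marsalt("anchor fractions must lie in (0, 1] and be non-increasing",
                  "marsalt_invalid_curve")
  }
  structure(list(model = "interpolant",
                 anchors = tibble::tibble(time_s = t, fraction = f)),
            class = "survival_curve")
}

#' Surviving fraction at a tumbling time
#'
#' Evaluates a [survival_curve()] at one or more times. For the interpolant,
#' times outside the anchor range error unless `extrapolate = TRUE`, in which
#' case the end segments are extended in log-log space (and the result is
#' capped at 1); extrapolated values should be treated as indicative only.
#'
#' @param curve A [survival_curve()].
#' @param time Tumbling time(s) in seconds, > 0. At one rotation (hop) per
#'   second this equals the hop count.
#' @param extrapolate Allow evaluation outside the anchor range
#'   (interpolant model only). Default `FALSE`.
#' @return Surviving fraction(s) in (0, 1].
#' @export
surviving_fraction <- function(curve, time, extrapolate = FALSE) {
  if (!inherits(curve, "survival_curve")) {
    abort_marsalt("curve must be a survival_curve", "marsalt_invalid_curve")
  }
  if (!is.numeric(time) || length(time) == 0L || any(!is.finite(time)) ||
      any(time <= 0)) {
    abort_marsalt("time must be positive and finite", "marsalt_invalid_time")
  }
  if (curve$model == "weibull") {
    return(exp(-(time / curve$scale)^curve$shape))
  }
  lt <- log(curve$anchors$time_s)
  lf <- log(curve$anchors$fraction)
  x <- log(time)
  if (!extrapolate && (any(x < lt[1L]) || any(x > lt[length(lt)]))) {
    abort_marsalt("time outside the anchor range; set extrapolate = TRUE to extend",
                  "marsalt_out_of_range")
  }
  # piecewise-linear in log-log space; end segments extended when extrapolating
  i <- findInterval(x, lt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lt) - 1L)
  slope <- (lf[i + 1L] - lf[i]) / (lt[i + 1L] - lt[i])
  out <- pmin(exp(lf[i] + slope * (x - lt[i])), 1)
  # anchor times return the anchor fraction itself, not its log/exp round trip
  hit <- match(time, curve$anchors$time_s)
  out[!is.na(hit)] <- curve$anchors$fraction[hit[!is.na(hit)]]
  out
}

#' Fit a Weibull survival model
#'
#' Least-squares fit of the Weibull survival form
#' \eqn{S(t) = \exp(-(t/\lambda)^k)} by linear regression of
#' \eqn{\log(-\log S)} on \eqn{\log t}: the slope is the shape `k` and the
#' intercept is \eqn{-k \log \lambda}. Points with fraction outside (0, 1)
#' cannot enter the linearisation and are dropped with a warning.
#'
#' On the digitized tumbling anchors the fitted shape is well below 1:
#' inactivation slows down dramatically, consistent with the observation that
#' spores surviving the first days of tumbling take ever longer to kill.
#'
#' @param time Times in seconds (positive, at least two distinct values after
#'   filtering).
#' @param fraction Surviving fractions, same length as `time`.
#' @return A list of class `weibull_fit` with elements `shape`, `scale`,
#'   `n_used`, and the underlying `lm` fit.
#' @examples
#' fit_weibull(c(60, 3600, 86400), c(0.5, 0.03, 0.005))$shape  # about 0.29
#' @export
fit_weibull <- function(time, fraction) {
  if (length(time) != length(fraction)) {
    abort_marsalt("time and fraction must have equal length",
                  "marsalt_fit_error")
  }
  keep <- is.finite(time) & is.finite(fraction) &
    time > 0 & fraction > 0 & fraction < 1
  if (any(!keep)) {
    warning(sprintf("dropping %d point(s) with fraction outside (0, 1)",
                    sum(!keep)))
  }
  t <- time[keep]
  f <- fraction[keep]
  if (length(t) < 2L || length(unique(t)) < 2L) {
    abort_marsalt("need >= 2 points with distinct positive times and fractions in (0, 1)",
                  "marsalt_fit_error")
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = log(t), y = log(-log(f))))
  k <- unname(stats::coef(fit)[2L])
  if (!is.finite(k) || k <= 0) {
    abort_marsalt("degenerate fit: non-positive Weibull shape",
                  "marsalt_fit_error")
  }
  lambda <- exp(-unname(stats::coef(fit)[1L]) / k)
  structure(list(shape = k, scale = lambda, n_used = length(t), lm = fit),
            class = "weibull_fit")
}

#' Time for the surviving population to halve
#'
#' For a Weibull curve, the time it takes the population surviving at time
#' `t0` to be halved again: the smallest `dt` with
#' `S(t0 + dt) = S(t0) / 2`. For shape `k < 1` this interval grows with `t0`
#' - each successive halving takes longer than the last, which is the formal
#' statement of the tumbling experiments' slowing inactivation.
#'
#' @param curve A Weibull-model [survival_curve()].
#' @param t0 Reference time(s), >= 0 (seconds).
#' @return Halving interval(s) in seconds.
#' @export
halving_time <- function(curve, t0) {
  if (!inherits(curve, "survival_curve") || curve$model != "weibull") {
    abort_marsalt("halving_time requires a weibull survival_curve",
                  "marsalt_invalid_curve")
  }
  if (any(!is.finite(t0)) || any(t0 < 0)) {
    abort_marsalt("t0 must be finite and >= 0", "marsalt_invalid_time")
  }
  k <- curve$shape
  lam <- curve$scale
  # solve (t0+dt)^k = t0^k + lambda^k * log 2
  lam * ((t0 / lam)^k + log(2))^(1 / k) - t0
}

#' Read or write survival anchors as CSV
#'
#' Two-column plain-text interchange (`time_s`, `fraction`) for survival
#' anchors.
#'
#' @param path File path.
#' @param anchors Data frame with columns `time_s` and `fraction`.
#' @return `read_anchors` returns a validated anchors tibble;
#'   `write_anchors` returns `path` invisibly.
#' @export
read_anchors <- function(path) {
  df <- utils::read.csv(path)
  curve <- survival_curve(df)  # validates
  curve$anchors
}

#' @rdname read_anchors
#' @export
write_anchors <- function(anchors, path) {
  utils::write.csv(anchors[, c("time_s", "fraction")], path, row.names = FALSE)
  invisible(path)
}
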