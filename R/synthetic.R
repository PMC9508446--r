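#' Configuration for a synthetic tumbling experiment
#'
#' Describes a simulated abrasive-tumbling assay: spores coated on grains are
#' tumbled, sampled at fixed times, plated, and colonies counted. The
#' generator draws CFU counts around `initial_cfu * S_true(t)` and emits a
#' paired untumbled control series (survival 1) at the same times, mirroring
#' the control group of the source assay design.
#'
#' Defaults: Weibull ground truth with shape 0.6 and scale 120 s (a
#' sub-exponential curve of the same character as the digitized tumbling
#' anchors - this truth is synthetic, not the experimental data), 200 CFU
#' initial plating scale, 3 replicates, and 20 sampling times log-spaced on
#' 10-1000 s so the expected count stays above a few CFU at the last time.
#'
#' @param true_curve Ground-truth [survival_curve()] (typically Weibull).
#' @param initial_cfu Expected colony count at time zero, >= 1.
#' @param sampling_times Strictly increasing positive times (s).
#' @param replicates Plates per time point, >= 1.
#' @param noise `"poisson"` for Poisson plating noise, `"none"` for
#'   expected-value counts (rounded to integers).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `synthetic_experiment_config`.
#' @export
synthetic_experiment_config <- function(
    true_curve = survival_curve(model = "weibull", shape = 0.6, scale = 120),
    initial_cfu = 200,
    sampling_times = exp(seq(log(10), log(1000), length.out = 20)),
    replicates = 3,
    noise = c("poisson", "none"),
    seed = 1L) {
  noise <- match.arg(noise)
  if (!inherits(true_curve, "survival_curve")) {
    abort_marsalt("true_curve must be a survival_curve",
                  "marsalt_invalid_config")
  }
  if (!is.numeric(initial_cfu) || length(initial_cfu) != 1L ||
      initial_cfu < 1) {
    abort_marsalt("initial_cfu must be >= 1", "marsalt_invalid_config")
  }
  if (length(sampling_times) < 1L || any(sampling_times <= 0) ||
      any(diff(sampling_times) <= 0)) {
    abort_marsalt("sampling_times must be positive and strictly increasing",
                  "marsalt_invalid_config")
  }
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1) {
    abort_marsalt("replicates must be >= 1", "marsalt_invalid_config")
  }
  structure(
    list(true_curve = true_curve, initial_cfu = initial_cfu,
         sampling_times = as.numeric(sampling_times),
         replicates = as.integer(replicates), noise = noise,
         seed = as.integer(seed)),
    class = "synthetic_experiment_config"
  )
}

#' Generate a synthetic tumbling-experiment table
#'
#' Draws colony counts for a tumbled series (expected count
#' `initial_cfu * S_true(t)`) and a paired untumbled control series
#' (expected count `initial_cfu`) at every sampling time and replicate.
#' With `noise = "poisson"` counts are Poisson draws; with `noise = "none"`
#' they are the expected values rounded to the nearest integer.
#'
#' @param config A [synthetic_experiment_config()].
#' @return A tibble with columns `group` ("tumbled"/"control"), `time_s`,
#'   `replicate`, `cfu` (non-negative integer).
#' @examples
#' cfg <- synthetic_experiment_config(seed = 42)
#' series <- generate_tumbling_series(cfg)
#' head(series)
#' @export
generate_tumbling_series <- function(config) {
  if (!inherits(config, "synthetic_experiment_config")) {
    abort_marsalt("config must be a synthetic_experiment_config",
                  "marsalt_invalid_config")
  }
  times <- config$sampling_times
  reps <- config$replicates
  s_true <- surviving_fraction(config$true_curve, times, extrapolate = TRUE)
  grid <- expand.grid(replicate = seq_len(reps), time_s = times,
                      KEEP.OUT.ATTRS = FALSE)
  mu_tumbled <- config$initial_cfu * rep(s_true, each = reps)
  mu_control <- rep(config$initial_cfu, nrow(grid))
  draw <- function(mu) {
    if (config$noise == "poisson") stats::rpois(length(mu), mu)
    else as.integer(round(mu))
  }
  counts <- with_local_seed(config$seed,
                            list(tumbled = draw(mu_tumbled),
                                 control = draw(mu_control)))
  tibble::tibble(
    group = rep(c("tumbled", "control"), each = nrow(grid)),
    time_s = rep(grid$time_s, 2L),
    replicate = rep(grid$replicate, 2L),
    cfu = as.integer(c(counts$tumbled, counts$control))
  )
}

#' Estimate survival fractions from a tumbling series
#'
#' Collapses a generated (or assay-shaped) CFU table to one empirical
#' surviving fraction per time point: the replicate-mean tumbled count
#' divided by the overall control mean (the plating-scale estimate).
#'
#' @param series A table as returned by [generate_tumbling_series()].
#' @return A tibble with columns `time_s` and `fraction`.
#' @export
estimate_survival <- function(series) {
  need <- c("group", "time_s", "replicate", "cfu")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    abort_marsalt("series must have columns group, time_s, replicate, cfu",
                  "marsalt_invalid_config")
  }
  control_mean <- mean(series$cfu[series$group == "control"])
  if (!is.finite(control_mean) || control_mean <= 0) {
    abort_marsalt("control series empty or zero; cannot normalise",
                  "marsalt_invalid_config")
  }
  tumbled <- series[series$group == "tumbled", ]
  agg <- stats::aggregate(cfu ~ time_s, data = tumbled, FUN = mean)
  tibble::tibble(time_s = agg$time_s, fraction = agg$cfu / control_mean)
}
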