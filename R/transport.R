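#' Tumbling protocol
#'
#' Maps laboratory tumbling to saltation: one rotation collision is taken to
#' correspond to one saltation hop. The default rotation rate of 1 rotation
#' per second is fixed by the experimental pairing of 1 minute of tumbling
#' with 60 hops.
#'
#' @param rotation_rate Rotations per second, > 0.
#' @param duration Tumbling duration in seconds, >= 0.
#' @return An object of class `tumbling_protocol`.
#' @export
tumbling_protocol <- function(rotation_rate = 1, duration) {
  if (!is.numeric(rotation_rate) || length(rotation_rate) != 1L ||
      !is.finite(rotation_rate) || rotation_rate <= 0) {
    abort_marsalt("rotation_rate must be a single positive number",
                  "marsalt_invalid_protocol")
  }
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration < 0) {
    abort_marsalt("duration must be a single non-negative number",
                  "marsalt_invalid_protocol")
  }
  structure(list(rotation_rate = rotation_rate, duration = duration),
            class = "tumbling_protocol")
}

#' Hop count from tumbling duration
#'
#' `rotation_rate * duration`, rounded half away from zero to the nearest
#' integer (the product is integral for all the canonical durations).
#'
#' @param protocol A [tumbling_protocol()].
#' @return Integer hop count.
#' @examples
#' hops_from_duration(tumbling_protocol(duration = 86400))  # 86400 hops
#' @export
hops_from_duration <- function(protocol) {
  if (!inherits(protocol, "tumbling_protocol")) {
    abort_marsalt("protocol must be a tumbling_protocol",
                  "marsalt_invalid_protocol")
  }
  x <- protocol$rotation_rate * protocol$duration
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

check_hops_length <- function(n_hops, hop_length) {
  if (!is.numeric(n_hops) || length(n_hops) != 1L || !is.finite(n_hops) ||
      n_hops < 0 || n_hops != round(n_hops)) {
    abort_marsalt("n_hops must be a single non-negative integer",
                  "marsalt_invalid_scenario")
  }
  if (!is.numeric(hop_length) || length(hop_length) != 1L ||
      !is.finite(hop_length) || hop_length < 0) {
    abort_marsalt("hop_length must be a single non-negative number",
                  "marsalt_invalid_scenario")
  }
}

#' Maximum (linear) travel distance
#'
#' Under a prevailing wind every hop points the same way, so hop distances
#' add linearly: `n_hops * hop_length`. This is the maximum-transport
#' end-member.
#'
#' @param n_hops Non-negative integer hop count.
#' @param hop_length Hop length in metres.
#' @return Distance in metres.
#' @export
linear_distance <- function(n_hops, hop_length) {
  check_hops_length(n_hops, hop_length)
  n_hops * hop_length
}

#' Minimum (random-walk) travel distance
#'
#' With no prevailing wind each hop is in a random direction and the grain
#' performs an isotropic fixed-step random walk; the root-mean-square net
#' displacement after n steps of length L is `sqrt(n) * L`. This is the
#' minimum-transport end-member.
#'
#' @inheritParams linear_distance
#' @return RMS net displacement in metres.
#' @export
random_walk_distance <- function(n_hops, hop_length) {
  check_hops_length(n_hops, hop_length)
  sqrt(n_hops) * hop_length
}

#' Monte Carlo saltation walk
#'
#' Simulates `n_walkers` grains each taking `n_hops` fixed-length hops on the
#' plane and summarises their net displacements. In `"prevailing_wind"` mode
#' every hop is collinear so every walker lands exactly `n_hops * hop_length`
#' downwind; in `"isotropic"` mode hop directions are uniform on [0, 2 pi)
#' and the RMS displacement converges to `sqrt(n_hops) * hop_length` (the
#' mean converges to `sqrt(pi)/2` times that). This validates the two
#' deterministic end-member bounds.
#'
#' @inheritParams linear_distance
#' @param mode `"isotropic"` or `"prevailing_wind"`.
#' @param n_walkers Number of independent walkers, >= 1.
#' @param seed Integer seed; the same seed reproduces the simulation exactly.
#' @return A list of class `walk_summary`: `mode`, `n_hops`, `hop_length`,
#'   `n_walkers`, `seed`, and summary statistics `mean`, `rms`, `max` (m)
#'   with `rms_se`, the delta-method standard error of the RMS estimate.
#' @examples
#' simulate_walk(100, 1, mode = "isotropic", n_walkers = 1000, seed = 1)$rms
#' @export
simulate_walk <- function(n_hops, hop_length,
                          mode = c("isotropic", "prevailing_wind"),
                          n_walkers = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  check_hops_length(n_hops, hop_length)
  if (!is.numeric(n_walkers) || length(n_walkers) != 1L ||
      !is.finite(n_walkers) || n_walkers < 1) {
    abort_marsalt("n_walkers must be >= 1", "marsalt_invalid_simulation")
  }
  n_walkers <- as.integer(n_walkers)

  if (mode == "prevailing_wind") {
    r <- rep(n_hops * hop_length, n_walkers)
  } else {
    r <- with_local_seed(seed, {
      out <- numeric(n_walkers)
      # chunk walkers so the angle matrix stays bounded in memory
      chunk <- max(1L, as.integer(5e6 %/% max(n_hops, 1L)))
      done <- 0L
      while (done < n_walkers) {
        m <- min(chunk, n_walkers - done)
        theta <- matrix(stats::runif(n_hops * m, 0, 2 * pi), nrow = n_hops)
        out[done + seq_len(m)] <- hop_length *
          sqrt(colSums(cos(theta))^2 + colSums(sin(theta))^2)
        done <- done + m
      }
      out
    })
  }
  r2 <- r^2
  rms <- sqrt(mean(r2))
  rms_se <- if (n_walkers > 1L && rms > 0) {
    stats::sd(r2) / sqrt(n_walkers) / (2 * rms)
  } else 0
  structure(
    list(mode = mode, n_hops = n_hops, hop_length = hop_length,
         n_walkers = n_walkers, seed = seed,
         mean = mean(r), rms = rms, rms_se = rms_se, max = max(r)),
    class = "walk_summary"
  )
}

#' Transport scenario and its end-member result
#'
#' Combines the physics layer with a hop count: computes the hop length for
#' the given environment/wind/particle, then both deterministic travel-bound
#' distances and, if a survival curve is supplied, the surviving fraction at
#' the corresponding tumbling time (hop count / rotation rate).
#'
#' @param env A [planetary_environment()].
#' @param wind A [wind_regime()].
#' @param particle A [particle_class()].
#' @param n_hops Non-negative integer hop count.
#' @param curve Optional [survival_curve()].
#' @param rotation_rate Rotations (hops) per second used to map hops back to
#'   tumbling time for the survival lookup.
#' @return A tibble with one row: `hop_length_m`, `linear_distance_m`,
#'   `random_walk_distance_m`, `surviving_fraction` (NA if no curve given).
#' @export
transport_result <- function(env = planetary_environment(),
                             wind = wind_regime(),
                             particle, n_hops,
                             curve = NULL, rotation_rate = 1) {
  L <- hop_length(env, wind, particle)
  sf <- NA_real_
  if (!is.null(curve) && n_hops > 0) {
    sf <- surviving_fraction(curve, n_hops / rotation_rate)
  }
  tibble::tibble(
    hop_length_m = L,
    linear_distance_m = linear_distance(n_hops, L),
    random_walk_distance_m = random_walk_distance(n_hops, L),
    surviving_fraction = sf
  )
}
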