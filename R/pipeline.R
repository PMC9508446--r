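#' Default configuration for the travel-distance and survival table
#'
#' Mars atmosphere and gravity, the midpoint shear velocity, the two grain
#' diameters considered (1 mm and 0.125 mm), the three tumbling durations
#' (1 minute, 1 hour, 1 day), one rotation (hop) per second, and the
#' digitized survival anchors.
#'
#' @return A named list understood by [build_table1()] and [run_report()].
#' @export
default_table1_config <- function() {
  list(
    environment = planetary_environment(),
    wind = wind_regime(),
    diameters = c("1 mm" = 1e-3, "0.125 mm" = 1.25e-4),
    durations = c("1 minute" = 60, "1 hour" = 3600, "1 day" = 86400),
    rotation_rate = 1,
    anchors = default_anchors()
  )
}

#' Read a key/value parameter file
#'
#' Reads saltation parameters from a Debian-control-format text file with
#' fields `eta`, `rho`, `g`, `u_star`, `u_star_t` and optionally `diameters`
#' (comma-separated metres); any field absent falls back to the Mars
#' default.
#'
#' @param path Path to the parameter file.
#' @return A configuration list as from [default_table1_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_marsalt(sprintf("config file not found: %s", path),
                  "marsalt_config_error")
  }
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(key, default) {
    if (is.null(raw[[key]])) default else as.numeric(raw[[key]])
  }
  cfg <- default_table1_config()
  cfg$environment <- planetary_environment(
    dynamic_viscosity = num("eta", 1.3e-5),
    fluid_density = num("rho", 0.02),
    gravity = num("g", 3.71))
  cfg$wind <- wind_regime(u_star = num("u_star", 1.45),
                          u_star_t = num("u_star_t", 1.12))
  if (!is.null(raw$diameters)) {
    d <- as.numeric(strsplit(raw$diameters, ",")[[1]])
    names(d) <- paste(format(d * 1e3, trim = TRUE), "mm")
    cfg$diameters <- d
  }
  cfg
}

#' Round a distance to the table's printed precision
#'
#' The published table rounds distances (in km) half away from zero to one
#' significant figure, except values in [10, 100) km, which carry two
#' significant figures (e.g. 23.8 km prints as 24, not 20). This convention
#' is reverse-engineered from the printed cells and documented as such.
#'
#' @param km Distance(s) in km.
#' @return Rounded distance(s) in km.
#' @export
round_table_distance <- function(km) {
  vapply(km, function(x) {
    if (!is.finite(x)) return(NA_real_)
    if (x == 0) return(0)
    digits <- if (abs(x) >= 10 && abs(x) < 100) 2L else 1L
    f <- 10^(floor(log10(abs(x))) - digits + 1L)
    sign(x) * floor(abs(x) / f + 0.5) * f
  }, numeric(1))
}

#' Build the travel-distance and survival table
#'
#' For each tumbling duration, computes the hop count, the minimum
#' (random-walk) and maximum (linear) travel distances for each particle
#' diameter, and the surviving percentage from the anchor interpolant.
#' Returned in both raw (unrounded km) and table-precision rounded form.
#'
#' Each rounded distance cell is checked for sensitivity to the rounding of
#' the hop length itself: a cell is flagged when recomputing it from the
#' hop length pre-rounded to the nearest metre changes the rounded result.
#' Flagged cells (notably the 1 mm / 1 day linear distance, ~2477 km
#' unrounded vs ~2506 km from a 29 m hop) reproduce the printed value only
#' under the unrounded-hop convention and are reported, never forced.
#'
#' @param config A configuration list, see [default_table1_config()].
#' @return A list with elements `raw` and `rounded` (tibbles with one row
#'   per duration and columns `tumbling_time`, `n_hops`,
#'   `min_km_<diameter>`, `max_km_<diameter>`, `surviving_percent`) and
#'   `flags`, a tibble of rounding-sensitive cells.
#' @examples
#' tab <- build_table1(default_table1_config())
#' tab$rounded
#' @export
build_table1 <- function(config = default_table1_config()) {
  need <- c("environment", "wind", "diameters", "durations",
            "rotation_rate", "anchors")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    abort_marsalt(paste("config missing keys:",
                        paste(missing, collapse = ", ")),
                  "marsalt_config_error")
  }
  curve <- survival_curve(config$anchors)
  hops <- unname(vapply(config$durations, function(dur) {
    hops_from_duration(tumbling_protocol(config$rotation_rate, dur))
  }, integer(1)))
  L <- vapply(config$diameters, function(d) {
    hop_length(config$environment, config$wind, particle_class(d))
  }, numeric(1))

  slug <- gsub("[^0-9a-z]", "", gsub("\\.", "p", tolower(names(config$diameters))))
  raw <- tibble::tibble(tumbling_time = names(config$durations),
                        n_hops = hops)
  rounded <- raw
  flags <- list()
  for (j in seq_along(L)) {
    mins <- vapply(hops, random_walk_distance, numeric(1),
                   hop_length = L[[j]]) / 1000
    maxs <- vapply(hops, linear_distance, numeric(1),
                   hop_length = L[[j]]) / 1000
    mins_alt <- vapply(hops, random_walk_distance, numeric(1),
                       hop_length = round(L[[j]])) / 1000
    maxs_alt <- vapply(hops, linear_distance, numeric(1),
                       hop_length = round(L[[j]])) / 1000
    raw[[paste0("min_km_", slug[j])]] <- mins
    raw[[paste0("max_km_", slug[j])]] <- maxs
    rounded[[paste0("min_km_", slug[j])]] <- round_table_distance(mins)
    rounded[[paste0("max_km_", slug[j])]] <- round_table_distance(maxs)
    for (i in seq_along(hops)) {
      for (kind in c("min", "max")) {
        v <- if (kind == "min") mins[i] else maxs[i]
        v_alt <- if (kind == "min") mins_alt[i] else maxs_alt[i]
        if (round_table_distance(v) != round_table_distance(v_alt)) {
          flags[[length(flags) + 1L]] <- tibble::tibble(
            tumbling_time = names(config$durations)[i],
            diameter = names(config$diameters)[j],
            column = kind,
            value_km = v,
            rounded_km = round_table_distance(v),
            rounded_km_from_rounded_hop = round_table_distance(v_alt),
            note = "rounded value depends on whether the hop length is first rounded to the nearest metre")
        }
      }
    }
  }
  surv <- 100 * vapply(hops, function(n) {
    if (n == 0) return(NA_real_)
    surviving_fraction(curve, n / config$rotation_rate)
  }, numeric(1))
  raw$surviving_percent <- surv
  rounded$surviving_percent <- surv
  flags <- if (length(flags)) do.call(rbind, flags) else
    tibble::tibble(tumbling_time = character(), diameter = character(),
                   column = character(), value_km = numeric(),
                   rounded_km = numeric(),
                   rounded_km_from_rounded_hop = numeric(),
                   note = character())
  list(raw = raw, rounded = rounded, flags = flags,
       hop_length_m = stats::setNames(unname(L), names(config$diameters)))
}

#' Run the full reproduction report
#'
#' Assembles the travel table plus a provenance block (parameters, package
#' version, seed) and optional Monte Carlo walk summaries validating the two
#' end-member distance formulas. Deterministic: the same configuration and
#' seed give an identical report.
#'
#' @param config Configuration list, see [default_table1_config()].
#' @param seed Integer seed used for the optional Monte Carlo walks.
#' @param include_walks Also run `simulate_walk` validations (isotropic and
#'   prevailing-wind) at a reduced hop count.
#' @param n_walkers Walkers per Monte Carlo validation.
#' @return A list of class `marsalt_report` with elements `parameters`,
#'   `table` (from [build_table1()]) and optionally `walks`.
#' @export
run_report <- function(config = default_table1_config(), seed = 1L,
                       include_walks = FALSE, n_walkers = 2000L) {
  tab <- build_table1(config)
  params <- list(
    eta = config$environment$dynamic_viscosity,
    rho = config$environment$fluid_density,
    g = config$environment$gravity,
    u_star = config$wind$u_star,
    u_star_t = config$wind$u_star_t,
    diameters_m = config$diameters,
    durations_s = config$durations,
    rotation_rate_hz = config$rotation_rate,
    anchors = config$anchors,
    package_version = as.character(utils::packageVersion("marsalt")),
    seed = as.integer(seed)
  )
  report <- list(parameters = params, table = tab)
  if (include_walks) {
    n <- min(config$durations)  # smallest duration keeps the walks cheap
    L1 <- tab$hop_length_m[[1L]]
    report$walks <- list(
      isotropic = simulate_walk(n, L1, mode = "isotropic",
                                n_walkers = n_walkers, seed = seed),
      prevailing = simulate_walk(n, L1, mode = "prevailing_wind",
                                 n_walkers = n_walkers, seed = seed)
    )
  }
  class(report) <- "marsalt_report"
  report
}

#' @export
print.marsalt_report <- function(x, ...) {
  cat("Saltation travel-distance and survival report\n")
  p <- x$parameters
  cat(sprintf("  eta=%g kg/m/s  rho=%g kg/m^3  g=%g m/s^2  u*=%g  u*t=%g m/s\n",
              p$eta, p$rho, p$g, p$u_star, p$u_star_t))
  cat(sprintf("  hop lengths: %s\n",
              paste(sprintf("%s -> %.1f m", names(x$table$hop_length_m),
                            x$table$hop_length_m), collapse = ", ")))
  cat("\nRounded table (km):\n")
  print(as.data.frame(x$table$rounded), row.names = FALSE)
  if (nrow(x$table$flags)) {
    cat("\nRounding-sensitive cells:\n")
    print(as.data.frame(x$table$flags[, c("tumbling_time", "diameter",
                                          "column", "value_km")]),
          row.names = FALSE)
  }
  invisible(x)
}
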