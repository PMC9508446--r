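#' Planetary environment for saltation
#'
#' Bundles the fluid and gravity parameters that set the saltation regime on a
#' planetary surface. Defaults are the Mars values used throughout:
#' atmospheric dynamic viscosity 1.3e-5 kg m^-1 s^-1, atmospheric density
#' 0.02 kg m^-3, surface gravity 3.71 m s^-2.
#'
#' @param dynamic_viscosity Fluid dynamic viscosity eta, kg m^-1 s^-1.
#' @param fluid_density Fluid density rho, kg m^-3.
#' @param gravity Surface gravitational acceleration g, m s^-2.
#' @return An object of class `planetary_environment`.
#' @examples
#' mars <- planetary_environment()
#' kinematic_viscosity(mars)  # 6.5e-4 m^2/s
#' @export
planetary_environment <- function(dynamic_viscosity = 1.3e-5,
                                  fluid_density = 0.02,
                                  gravity = 3.71) {
  for (nm in c("dynamic_viscosity", "fluid_density", "gravity")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      abort_marsalt(sprintf("%s must be a single positive finite number", nm),
                    "marsalt_invalid_environment")
    }
  }
  structure(
    list(dynamic_viscosity = dynamic_viscosity,
         fluid_density = fluid_density,
         gravity = gravity),
    class = "planetary_environment"
  )
}

#' Wind regime for saltation
#'
#' Shear (friction) velocity `u_star` and impact-threshold wind speed
#' `u_star_t`. Sustained saltation requires `u_star >= u_star_t`. Mars
#' defaults: the threshold is 1.12 m/s and the shear velocity is taken as
#' 1.45 m/s, the midpoint of the estimated 1.12-1.78 m/s range.
#'
#' @param u_star Shear velocity, m/s.
#' @param u_star_t Impact-threshold wind speed, m/s.
#' @return An object of class `wind_regime`.
#' @export
wind_regime <- function(u_star = 1.45, u_star_t = 1.12) {
  if (!is.numeric(u_star) || length(u_star) != 1L || !is.finite(u_star) ||
      u_star <= 0 ||
      !is.numeric(u_star_t) || length(u_star_t) != 1L || !is.finite(u_star_t) ||
      u_star_t <= 0) {
    abort_marsalt("u_star and u_star_t must be single positive finite numbers",
                  "marsalt_invalid_wind")
  }
  structure(list(u_star = u_star, u_star_t = u_star_t), class = "wind_regime")
}

#' Saltating particle class
#'
#' @param diameter Particle diameter d in metres (e.g. `1e-3` for 1 mm sand,
#'   `1.25e-4` for 125-micron grains).
#' @return An object of class `particle_class`.
#' @export
particle_class <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0) {
    abort_marsalt("particle diameter must be a single positive finite number",
                  "marsalt_invalid_particle")
  }
  structure(list(diameter = diameter), class = "particle_class")
}

#' Kinematic viscosity of the atmosphere
#'
#' @param env A [planetary_environment()].
#' @return Kinematic viscosity eta/rho in m^2/s.
#' @export
kinematic_viscosity <- function(env) {
  if (!inherits(env, "planetary_environment")) {
    abort_marsalt("env must be a planetary_environment",
                  "marsalt_invalid_environment")
  }
  env$dynamic_viscosity / env$fluid_density
}

#' Saltation hop length
#'
#' Characteristic horizontal length of a single saltation hop,
#' \deqn{L_{salt} = 1091.5 \, (v^2/g)^{1/3} \, (u_* - u_{*t}) / \sqrt{g d},}
#' with \eqn{v} the kinematic viscosity of the atmosphere, \eqn{g} surface
#' gravity, \eqn{d} particle diameter, \eqn{u_*} the shear velocity and
#' \eqn{u_{*t}} the impact threshold. The hop length scales as
#' \eqn{d^{-1/2}}: smaller grains hop farther. With the Mars defaults this
#' gives about 29 m for 1 mm grains and 81 m for 0.125 mm grains.
#'
#' @param env A [planetary_environment()].
#' @param wind A [wind_regime()]; requires `u_star >= u_star_t`.
#' @param particle A [particle_class()].
#' @return Hop length in metres (0 exactly at the threshold
#'   `u_star == u_star_t`).
#' @examples
#' hop_length(planetary_environment(), wind_regime(), particle_class(1e-3))
#' @export
hop_length <- function(env = planetary_environment(),
                       wind = wind_regime(),
                       particle) {
  if (!inherits(wind, "wind_regime")) {
    abort_marsalt("wind must be a wind_regime", "marsalt_invalid_wind")
  }
  if (!inherits(particle, "particle_class")) {
    abort_marsalt("particle must be a particle_class",
                  "marsalt_invalid_particle")
  }
  if (wind$u_star < wind$u_star_t) {
    abort_marsalt(
      "shear velocity below impact threshold: no sustained saltation",
      "marsalt_below_threshold")
  }
  v <- kinematic_viscosity(env)
  g <- env$gravity
  1091.5 * (v^2 / g)^(1 / 3) * (wind$u_star - wind$u_star_t) /
    sqrt(g * particle$diameter)
}
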