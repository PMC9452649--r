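#' Simulation configuration for a synthetic basketball cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort
#' structure (two teams, role mix), session calendar, per-role intensity
#' band occupancy, finals effects, trace synthesis settings and seeds.
#' Defaults describe a two-team semi-professional season: a 10-player
#' women's team and a 13-player men's team, 90-min training sessions
#' (range 84--100 min), 94-min monitored match windows, and per-role band
#' occupancy and playing-time distributions typical of starters,
#' in-rotation bench and out-rotation bench players, with planted
#' finals shifts (starters gain about 4.4 min of playing time, less
#' inactive time; out-rotation bench players lose about 2.1 min and
#' high-intensity work). Default session counts are sized so the cohort
#' yields 387 regular-season and 75 finals match observations and 445
#' regular-season and 113 finals training observations.
#'
#' @param seed integer master seed; every stochastic draw in the
#'   generator descends from it, so identical configs give identical
#'   cohorts.
#' @param n_players named integer vector, players per team.
#' @param sample_rate trace sampling rate, Hz.
#' @param epoch_length epoch used for banding, seconds.
#' @param match_duration monitored match window (first to final quarter,
#'   stoppages included), minutes.
#' @param training_duration typical training session length, minutes.
#' @param training_duration_range attainable training lengths, minutes.
#' @param role_mix list (one element per team) of named counts of
#'   starter / in_rotation / out_rotation players.
#' @param sessions list (one element per team) of named session counts:
#'   `training_regular`, `match_regular`, `training_finals`,
#'   `match_finals`.
#' @param observation_targets named integer vector of total
#'   player-session observations per `(type, period)` cell; attendance is
#'   thinned deterministically to hit these exactly.
#' @param band_occupancy list with `match` (per-role) and `training`
#'   (all-roles) occupancy fractions over the five intensity bands; each
#'   vector must sum to 1.
#' @param occupancy_shift_finals list with `match` (per-role) and
#'   `training` additive shifts applied to occupancy in finals
#'   (fractions, re-normalized after shifting).
#' @param occupancy_jitter_sd log-scale between-session occupancy
#'   variability (logistic-normal).
#' @param minutes_model per-role playing-time model: mean, between-player
#'   SD and within-player SD, minutes.
#' @param minutes_shift_finals per-role additive playing-time shift in
#'   finals, minutes.
#' @param bout_length list of `active` and `recovery` bout-length
#'   mean/sd, seconds (truncated log-normal, minimum `bout_min`).
#' @param bout_min minimum bout length, seconds.
#' @param noise_sd white accelerometer noise SD per axis, g.
#' @param yoyo_speeds Yo-Yo IR1 stage speed ladder, km/h.
#' @param calib_noise_sd stage-level AvF_NET noise in calibration
#'   records, newtons.
#' @param vo2_rest resting oxygen uptake, ml·kg^-1·min^-1.
#' @param mass_model,vo2max_model per-team sampling distributions
#'   (mean, sd, min, max) for body mass (kg) and VO2max
#'   (ml·kg^-1·min^-1).
#'
#' @return A validated list of class `sim_config`.
#' @seealso [generate_cohort()], [generate_roster()]
#' @export
sim_config <- function(
    seed = 1L,
    n_players = c(women = 10L, men = 13L),
    sample_rate = 100,
    epoch_length = 1,
    match_duration = 94,
    training_duration = 90,
    training_duration_range = c(84, 100),
    role_mix = list(
      women = c(starter = 5L, in_rotation = 2L, out_rotation = 3L),
      men   = c(starter = 5L, in_rotation = 2L, out_rotation = 6L)),
    sessions = list(
      women = c(training_regular = 26L, match_regular = 20L,
                training_finals = 4L, match_finals = 3L),
      men   = c(training_regular = 24L, match_regular = 20L,
                training_finals = 8L, match_finals = 4L)),
    observation_targets = c(match_regular = 387L, match_finals = 75L,
                            training_regular = 445L,
                            training_finals = 113L),
    band_occupancy = list(
      match = list(
        starter      = c(60.5, 15.7, 16.1, 3.2, 4.4) / 99.9,
        in_rotation  = c(75.8,  8.5,  9.8, 2.1, 2.8) / 99.0,
        out_rotation = c(85.9,  9.5,  4.2, 0.6, 0.7) / 100.9),
      training       = c(59.8, 16.4, 16.9, 2.6, 2.8) / 98.5),
    occupancy_shift_finals = list(
      match = list(
        starter      = c(-4.8,  2.8,  1.9,  0.4,  0.0) / 100,
        in_rotation  = c(-1.8,  2.0,  1.0, -0.4, -0.8) / 100,
        out_rotation = c( 2.7, -0.2, -1.3, -0.3, -0.4) / 100),
      training       = c(-3.5,  0.2,  2.4,  0.7,  0.3) / 100),
    occupancy_jitter_sd = 0.15,
    minutes_model = list(
      starter      = c(mean = 29.5, between_sd = 3.0, within_sd = 4.0),
      in_rotation  = c(mean = 17.5, between_sd = 2.0, within_sd = 3.0),
      out_rotation = c(mean = 4.5,  between_sd = 1.0, within_sd = 2.0)),
    minutes_shift_finals = c(starter = 4.4, in_rotation = 0,
                             out_rotation = -2.1),
    bout_length = list(active = c(mean = 6, sd = 3),
                       recovery = c(mean = 12, sd = 8)),
    bout_min = 2,
    noise_sd = 0.02,
    yoyo_speeds = c(10, 12, 13, 13.5, 14, 14.5, 15, 15.5, 16, 16.5, 17),
    calib_noise_sd = 4,
    vo2_rest = 3.5,
    mass_model = list(
      women = c(mean = 76.5, sd = 19.5, min = 45, max = 130),
      men   = c(mean = 96.2, sd = 16.4, min = 55, max = 140)),
    vo2max_model = list(
      women = c(mean = 44, sd = 4, min = 35, max = 60),
      men   = c(mean = 52, sd = 5, min = 40, max = 68))) {
  cfg <- structure(
    list(seed = as.integer(seed), n_players = n_players,
         sample_rate = sample_rate, epoch_length = epoch_length,
         match_duration = match_duration,
         training_duration = training_duration,
         training_duration_range = training_duration_range,
         role_mix = role_mix, sessions = sessions,
         observation_targets = observation_targets,
         band_occupancy = band_occupancy,
         occupancy_shift_finals = occupancy_shift_finals,
         occupancy_jitter_sd = occupancy_jitter_sd,
         minutes_model = minutes_model,
         minutes_shift_finals = minutes_shift_finals,
         bout_length = bout_length, bout_min = bout_min,
         noise_sd = noise_sd, yoyo_speeds = yoyo_speeds,
         calib_noise_sd = calib_noise_sd, vo2_rest = vo2_rest,
         mass_model = mass_model, vo2max_model = vo2max_model),
    class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks structural invariants: strictly positive counts, rates and
#' durations; per-role band occupancy summing to one (tolerance 1e-9);
#' role mixes consistent with team sizes; matching team names across
#' fields. Called by [sim_config()]; exported so externally assembled
#' configs can be checked too.
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly-validated (errors on violation).
#' @export
validate_sim_config <- function(cfg) {
  teams <- names(cfg$n_players)
  if (is.null(teams) || any(!nzchar(teams)))
    stop_("config error: n_players must be a named vector of teams")
  if (any(cfg$n_players <= 0))
    stop_("config error: n_players must be strictly positive")
  for (f in c("sample_rate", "epoch_length", "match_duration",
              "training_duration", "bout_min"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop_("config error: ", f, " must be a positive scalar")
  if (cfg$noise_sd < 0 || cfg$calib_noise_sd < 0 ||
      cfg$occupancy_jitter_sd < 0)
    stop_("config error: noise SDs must be non-negative")
  if (!setequal(names(cfg$role_mix), teams) ||
      !setequal(names(cfg$sessions), teams))
    stop_("config error: role_mix and sessions must cover every team")
  for (tm in teams) {
    if (sum(cfg$role_mix[[tm]]) != cfg$n_players[[tm]])
      stop_("config error: role_mix for team '", tm,
            "' does not sum to its player count")
    if (any(cfg$sessions[[tm]] < 0))
      stop_("config error: negative session count for team '", tm, "'")
  }
  occs <- c(cfg$band_occupancy$match,
            list(training = cfg$band_occupancy$training))
  for (nm in names(occs)) {
    o <- occs[[nm]]
    if (length(o) != 5 || any(o < 0))
      stop_("config error: band occupancy '", nm,
            "' must be 5 non-negative fractions")
    if (abs(sum(o) - 1) > 1e-9)
      stop_("config error: band occupancy '", nm,
            "' must sum to 1 (got ", format(sum(o), digits = 12), ")")
  }
  if (length(cfg$yoyo_speeds) < 2 || any(diff(cfg$yoyo_speeds) <= 0))
    stop_("config error: yoyo_speeds must be an increasing ladder")
  for (b in cfg$bout_length)
    if (any(b <= 0)) stop_("config error: bout lengths must be positive")
  cfg
}

# Truncated-normal draw by rejection with clamping fallback.
rnorm_trunc_ <- function(n, mean, sd, min = -Inf, max = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < min | x > max)
  for (i in seq_len(25)) {
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < min | x[bad] > max]
  }
  pmin(pmax(x, min), max)
}

# Logistic-normal jitter of an occupancy vector (rows = draws).
jitter_occupancy_ <- function(target, n, sd) {
  base <- log(pmax(target, 1e-6))
  m <- matrix(base, nrow = n, ncol = 5, byrow = TRUE) +
    matrix(rnorm(n * 5, 0, sd), nrow = n)
  e <- exp(m)
  e / rowSums(e)
}

# Occupancy target for a (type, role, period) cell, shifts applied and
# re-normalized.
occupancy_target_ <- function(cfg, type, role, period) {
  if (type == "match") {
    occ <- cfg$band_occupancy$match[[role]]
    if (period == "finals")
      occ <- occ + cfg$occupancy_shift_finals$match[[role]]
  } else {
    occ <- cfg$band_occupancy$training
    if (period == "finals") occ <- occ + cfg$occupancy_shift_finals$training
  }
  occ <- pmax(occ, 1e-4)
  occ / sum(occ)
}
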