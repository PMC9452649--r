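#' Generate a synthetic player roster
#'
#' Draws one player record per roster slot: team, sex, body mass and
#' VO2max from the configured per-team truncated-normal distributions,
#' plus the planted role (starter / in-rotation / out-rotation bench)
#' used downstream to plant playing time and band occupancy. A planted
#' calibration line (slope, intercept of the VO2 ~ AvF_NET relationship)
#' is attached per player; its slope scales inversely with body mass so
#' heavier players produce larger forces for the same metabolic cost.
#'
#' @param config a [sim_config()].
#' @return Data frame with columns `player_id, team, sex, mass_kg,
#'   vo2max_mlkgmin, role_planted, calib_slope_true,
#'   calib_intercept_true`.
#' @export
generate_roster <- function(config) {
  validate_sim_config(config)
  with_seed_(config$seed, {
    rows <- lapply(names(config$n_players), function(tm) {
      n <- config$n_players[[tm]]
      mm <- config$mass_model[[tm]]
      vm <- config$vo2max_model[[tm]]
      mass <- rnorm_trunc_(n, mm[["mean"]], mm[["sd"]], mm[["min"]],
                           mm[["max"]])
      vo2max <- rnorm_trunc_(n, vm[["mean"]], vm[["sd"]], vm[["min"]],
                             vm[["max"]])
      mix <- config$role_mix[[tm]]
      data.frame(
        player_id = sprintf("%s_%02d", tm, seq_len(n)),
        team = tm,
        sex = switch(tm, women = "F", men = "M", NA_character_),
        mass_kg = mass,
        vo2max_mlkgmin = vo2max,
        role_planted = rep(ROLE_LEVELS, times = mix[ROLE_LEVELS]),
        stringsAsFactors = FALSE)
    })
    roster <- do.call(rbind, rows)
    # planted calibration line: VO2 = intercept + slope * F
    roster$calib_slope_true <- 8 / roster$mass_kg
    roster$calib_intercept_true <- config$vo2_rest
    roster
  })
}

#' Generate synthetic Yo-Yo IR1 calibration stages for one player
#'
#' Builds the player's completed stages of the Yo-Yo IR1 speed ladder
#' (every configured stage whose ACSM-estimated VO2 does not exceed the
#' player's VO2max, minimum four stages) and generates a per-stage
#' AvF_NET as the planted linear relationship evaluated at the stage VO2
#' plus Gaussian stage noise. Downstream calibration fits should recover
#' the planted coefficients exactly when `calib_noise_sd = 0`.
#'
#' @param player one roster row (from [generate_roster()]).
#' @param config a [sim_config()].
#' @param n_stages optional explicit number of ladder stages (>= 2).
#' @return Data frame `player_id, stage, speed_kmh, vo2_mlkgmin,
#'   avf_net_n` with the planted `slope_true`/`intercept_true` as
#'   attributes.
#' @export
generate_yoyo_stages <- function(player, config, n_stages = NULL) {
  speeds <- config$yoyo_speeds
  if (!is.null(n_stages)) {
    if (n_stages < 2)
      stop_("at least 2 stages are needed to identify a line")
    speeds <- head(speeds, n_stages)
  } else {
    vo2 <- estimate_vo2_for_speed(speeds)
    keep <- vo2 <= player$vo2max_mlkgmin
    speeds <- speeds[seq_len(max(sum(keep), min(4, length(speeds))))]
  }
  vo2 <- estimate_vo2_for_speed(speeds)
  truth_f <- (vo2 - player$calib_intercept_true) / player$calib_slope_true
  avf <- truth_f + rnorm(length(speeds), 0, config$calib_noise_sd)
  structure(
    data.frame(player_id = player$player_id, stage = seq_along(speeds),
               speed_kmh = speeds, vo2_mlkgmin = vo2, avf_net_n = avf,
               stringsAsFactors = FALSE),
    slope_true = player$calib_slope_true,
    intercept_true = player$calib_intercept_true)
}

#' Calibrate every rostered player from synthetic stage data
#'
#' Generates Yo-Yo stages for each player, fits the linear calibration
#' ([fit_calibration()]) and derives personalized band thresholds
#' ([bands_for_player()]). VO2max for band construction is the player's
#' rostered VO2max (the estimated VO2 of the final completed stage by
#' construction of the stage list).
#'
#' @param roster data frame from [generate_roster()].
#' @param config a [sim_config()].
#' @return List with `stages` (stacked stage records), `models` and
#'   `bands` (both named by player id).
#' @export
generate_calibration <- function(roster, config) {
  seeds <- derive_seeds_(config$seed + 1L, nrow(roster))
  stages <- vector("list", nrow(roster))
  models <- bands <- setNames(vector("list", nrow(roster)),
                              roster$player_id)
  for (i in seq_len(nrow(roster))) {
    p <- roster[i, ]
    st <- with_seed_(seeds[i], generate_yoyo_stages(p, config))
    models[[p$player_id]] <- fit_calibration(
      st$avf_net_n, st$vo2_mlkgmin, vo2_rest = config$vo2_rest,
      vo2_max = max(st$vo2_mlkgmin), player_id = p$player_id)
    bands[[p$player_id]] <- bands_for_player(models[[p$player_id]])
    stages[[i]] <- st
  }
  list(stages = do.call(rbind, stages), models = models, bands = bands)
}
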