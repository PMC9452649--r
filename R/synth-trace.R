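# Log-normal parameters from a target mean/sd on the natural scale.
lnorm_params_ <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Largest-remainder rounding of fractional epoch quotas to integers
# summing exactly to n_epochs.
round_quota_ <- function(occupancy, n_epochs) {
  raw <- occupancy * n_epochs
  q <- floor(raw)
  short <- n_epochs - sum(q)
  if (short > 0) {
    add <- order(raw - q, decreasing = TRUE)[seq_len(short)]
    q[add] <- q[add] + 1
  }
  q
}

#' Build a bout schedule with target band occupancy
#'
#' Lays out a session as alternating recovery (inactive) and active
#' bouts whose per-band epoch totals equal the largest-remainder
#' rounding of `occupancy * n_epochs` exactly. Bout lengths are drawn
#' from truncated log-normal distributions (separate active/recovery
#' parameters, minimum `bout_min` seconds) and expressed in whole
#' epochs so bout edges align with epoch boundaries. Active bout bands
#' are drawn with probability proportional to the remaining quota.
#' Uses the ambient RNG stream.
#'
#' @param n_epochs session length in epochs.
#' @param occupancy 5 band fractions summing to 1.
#' @param config a [sim_config()] (bout-length settings).
#' @return Data frame `band` (factor) and `epochs` (integer), with the
#'   per-band epoch quota as attribute `band_epochs`.
#' @export
build_bout_schedule <- function(n_epochs, occupancy, config) {
  if (abs(sum(occupancy) - 1) > 1e-9)
    stop_("occupancy fractions must sum to 1")
  quota <- round_quota_(occupancy, n_epochs)
  planted <- setNames(quota, BAND_LEVELS)
  min_ep <- max(1L, ceiling(config$bout_min / config$epoch_length))
  pa <- lnorm_params_(config$bout_length$active[["mean"]],
                      config$bout_length$active[["sd"]])
  pr <- lnorm_params_(config$bout_length$recovery[["mean"]],
                      config$bout_length$recovery[["sd"]])
  bands <- integer(0); lens <- integer(0)
  recovery_turn <- TRUE
  while (sum(quota) > 0) {
    if (recovery_turn && quota[1] > 0) {
      band <- 1L
      raw <- rlnorm(1, pr[1], pr[2])
    } else if (any(quota[2:5] > 0)) {
      band <- 1L + sample.int(4L, 1L, prob = quota[2:5])
      raw <- rlnorm(1, pa[1], pa[2])
    } else {
      band <- 1L
      raw <- rlnorm(1, pr[1], pr[2])
    }
    len <- min(quota[band],
               max(min_ep, as.integer(round(raw / config$epoch_length))))
    quota[band] <- quota[band] - len
    bands <- c(bands, band); lens <- c(lens, len)
    recovery_turn <- band != 1L
  }
  structure(data.frame(band = factor(BAND_LEVELS[bands],
                                     levels = BAND_LEVELS),
                       epochs = lens),
            band_epochs = planted)
}

# Synthesize a 100 Hz trace from a bout schedule. Within each bout the
# oscillatory axis carries an integer-frequency sinusoid whose rectified
# mean equals the bout's target resultant magnitude (mean |A sin| =
# 2A/pi), so epoch-mean magnitudes hit the planted band centre; a 1 g
# gravity offset rides on the z axis and white noise on all three.
synthesize_trace_ <- function(schedule, centers_n, mass, config,
                              player_id = NA_character_,
                              session_id = NA_character_) {
  fs <- config$sample_rate
  per_epoch <- round(fs * config$epoch_length)
  segs <- lapply(seq_len(nrow(schedule)), function(i) {
    n <- schedule$epochs[i] * per_epoch
    target_g <- centers_n[as.integer(schedule$band[i])] / (9.81 * mass)
    amp <- target_g * pi / 2
    f <- sample(1:4, 1)
    phase <- runif(1, 0, 2 * pi)
    amp * sin(2 * pi * f * (seq_len(n) - 1) / fs + phase)
  })
  ax <- unlist(segs, use.names = FALSE)
  n <- length(ax)
  if (config$noise_sd > 0) {
    ax <- ax + rnorm(n, 0, config$noise_sd)
    ay <- rnorm(n, 0, config$noise_sd)
    az <- 1 + rnorm(n, 0, config$noise_sd)
  } else {
    ay <- numeric(n)
    az <- rep(1, n)
  }
  accel_trace(ax, ay, az, fs, player_id = player_id,
              session_id = session_id)
}

#' Generate one synthetic session trace with known ground truth
#'
#' Produces a raw triaxial trace for a player-session whose epoch-level
#' band occupancy after the full filtering pipeline approximates the
#' planted fractions, plus the planted truth itself. Intensity within a
#' bout targets the centre of its band (in newtons, via the player's
#' band thresholds), so recovered band minutes are robust to filter
#' edge effects at bout boundaries.
#'
#' @param player roster row (needs `mass_kg`, `player_id`).
#' @param session_spec list with `session_type` ("training"/"match"),
#'   `season_period` ("regular"/"finals"), `role`, `duration_min`, and
#'   optionally `occupancy` (5 fractions overriding the configured
#'   target) and `session_id`.
#' @param bands the player's [bands_for_player()] thresholds.
#' @param config a [sim_config()].
#' @param seed optional seed for this session (defaults to the config
#'   seed).
#' @return List with `trace` (an [accel_trace()]) and `ground_truth`
#'   (planted per-band epochs and minutes, schedule, band centres).
#' @export
generate_session_trace <- function(player, session_spec, bands, config,
                                   seed = config$seed) {
  occ <- session_spec$occupancy
  if (is.null(occ))
    occ <- occupancy_target_(config, session_spec$session_type,
                             session_spec$role,
                             session_spec$season_period)
  if (abs(sum(occ) - 1) > 1e-9)
    stop_("occupancy fractions must sum to 1")
  n_epochs <- round(session_spec$duration_min * 60 / config$epoch_length)
  centers <- band_centers(bands)
  with_seed_(seed, {
    sched <- build_bout_schedule(n_epochs, occ, config)
    trace <- synthesize_trace_(
      sched, centers, player$mass_kg, config,
      player_id = player$player_id,
      session_id = session_spec$session_id %||% NA_character_)
    planted <- attr(sched, "band_epochs")
    list(trace = trace,
         ground_truth = list(
           band_epochs = planted,
           band_minutes = planted * config$epoch_length / 60,
           schedule = sched, centers_n = centers,
           duration_min = session_spec$duration_min))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
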