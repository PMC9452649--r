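# Small fixtures built in code.

# A minimal cohort config: 2 players per team, short sessions, full
# attendance (targets equal capacity), so trace-level runs stay fast.
tiny_config <- function(seed = 1, ...) {
  sessions <- list(
    women = c(training_regular = 2L, match_regular = 2L,
              training_finals = 1L, match_finals = 1L),
    men   = c(training_regular = 2L, match_regular = 2L,
              training_finals = 1L, match_finals = 1L))
  n_players <- c(women = 2L, men = 2L)
  targets <- c(
    match_regular = sum(vapply(names(sessions), function(tm)
      n_players[[tm]] * sessions[[tm]][["match_regular"]], numeric(1))),
    match_finals = sum(vapply(names(sessions), function(tm)
      n_players[[tm]] * sessions[[tm]][["match_finals"]], numeric(1))),
    training_regular = sum(vapply(names(sessions), function(tm)
      n_players[[tm]] * sessions[[tm]][["training_regular"]],
      numeric(1))),
    training_finals = sum(vapply(names(sessions), function(tm)
      n_players[[tm]] * sessions[[tm]][["training_finals"]],
      numeric(1))))
  sim_config(
    seed = seed, n_players = n_players,
    role_mix = list(women = c(starter = 1L, in_rotation = 1L,
                              out_rotation = 0L),
                    men = c(starter = 1L, in_rotation = 1L,
                            out_rotation = 0L)),
    sessions = sessions, observation_targets = targets,
    match_duration = 6, training_duration = 5,
    training_duration_range = c(4, 6), ...)
}

# A clean calibration model: slope 0.1, intercept = rest = 3.5,
# max 53.5 -> thresholds at 50/200/450/500 N.
clean_model <- function() {
  fit_calibration(avf_net = c(100, 200, 300, 400),
                  vo2 = 3.5 + 0.1 * c(100, 200, 300, 400),
                  vo2_rest = 3.5, vo2_max = 53.5, player_id = "p1")
}

band_cols <- paste0("epochs_", c("inactive", "light",
                                 "moderate_vigorous", "maximal",
                                 "supramaximal"))

# Analysis frame with planted effects, built directly (no cohort):
# k subjects split over roles/teams, n sessions per period, normal
# noise. Used for decision-tree behavior tests.
planted_frame <- function(k = 12, n_per_period = 8, sd = 1,
                          period_effect = 0, role_period = NULL,
                          three_way = 0, seed = 1) {
  roles <- c("starter", "in_rotation", "out_rotation")
  set.seed(seed)
  grid <- expand.grid(player = seq_len(k),
                      session = seq_len(2 * n_per_period))
  d <- data.frame(
    player_id = sprintf("p%02d", grid$player),
    role = roles[(grid$player - 1) %% 3 + 1],
    team = c("women", "men")[(grid$player - 1) %/% (k / 2) + 1],
    season_period = ifelse(grid$session <= n_per_period, "regular",
                           "finals"))
  u <- rnorm(k, 0, 0.5)
  y <- u[grid$player] + rnorm(nrow(d), 0, sd)
  fin <- d$season_period == "finals"
  y <- y + period_effect * fin
  if (!is.null(role_period))
    y <- y + role_period[d$role] * fin
  y <- y + three_way * fin * (d$role == "starter") * (d$team == "men")
  d$y <- y
  d
}
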