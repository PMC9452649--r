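test_that("roster has the configured size, teams and positive masses", {
  roster <- generate_roster(sim_config(seed = 3))
  expect_equal(nrow(roster), 23)  # 10 women + 13 men
  expect_equal(sum(roster$team == "women"), 10)
  expect_equal(sum(roster$team == "men"), 13)
  expect_true(all(roster$mass_kg > 0))
  expect_error(sim_config(n_players = c(women = 0, men = 13)),
               "positive")
})

test_that("roster generation is deterministic under a seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(generate_roster(cfg), generate_roster(cfg))
})

test_that("degenerate mass distribution collapses to its mean", {
  cfg <- sim_config(seed = 5, mass_model = list(
    women = c(mean = 76.5, sd = 0, min = 45, max = 130),
    men = c(mean = 96.2, sd = 0, min = 55, max = 140)))
  roster <- generate_roster(cfg)
  expect_true(all(roster$mass_kg[roster$team == "women"] == 76.5))
})

test_that("Yo-Yo stages are increasing and noiseless stages sit on the planted line", {
  cfg <- sim_config(seed = 2, calib_noise_sd = 0,
                    yoyo_speeds = c(10, 11, 12, 13))
  roster <- generate_roster(cfg)
  st <- generate_yoyo_stages(roster[1, ], cfg, n_stages = 4)
  expect_equal(st$speed_kmh, c(10, 11, 12, 13))
  expect_true(all(diff(st$speed_kmh) > 0))
  planted <- (st$vo2_mlkgmin - attr(st, "intercept_true")) /
    attr(st, "slope_true")
  expect_equal(st$avf_net_n, planted, tolerance = 1e-12)
  # downstream fit recovers the planted coefficients
  m <- fit_calibration(st$avf_net_n, st$vo2_mlkgmin,
                       vo2_rest = cfg$vo2_rest)
  expect_equal(m$slope, attr(st, "slope_true"), tolerance = 1e-6)
  expect_equal(m$intercept, attr(st, "intercept_true"),
               tolerance = 1e-6)
  expect_error(generate_yoyo_stages(roster[1, ], cfg, n_stages = 1),
               "2 stages")
})

test_that("config validation enforces occupancy and structural invariants", {
  expect_error(sim_config(band_occupancy = list(
    match = list(starter = c(0.5, 0.2, 0.2, 0.05, 0.04),
                 in_rotation = rep(0.2, 5),
                 out_rotation = rep(0.2, 5)),
    training = rep(0.2, 5))), "sum to 1")
  expect_error(sim_config(role_mix = list(
    women = c(starter = 5L, in_rotation = 2L, out_rotation = 2L),
    men = c(starter = 5L, in_rotation = 2L, out_rotation = 6L))),
    "role_mix")
  expect_error(sim_config(match_duration = -1), "positive")
})

test_that("bout schedules hit the planted per-band epoch quota exactly", {
  cfg <- tiny_config()
  set.seed(42)
  occ <- c(0.6, 0.15, 0.17, 0.03, 0.05)
  sch <- build_bout_schedule(3600, occ, cfg)
  tally <- tapply(sch$epochs, sch$band, sum, default = 0L)
  expect_equal(sum(sch$epochs), 3600)
  expect_equal(as.numeric(tally), as.numeric(attr(sch, "band_epochs")))
  expect_equal(sum(attr(sch, "band_epochs")), 3600)
  expect_error(build_bout_schedule(100, c(0.5, 0.5, 0.2, 0, 0), cfg),
               "sum to 1")
})

test_that("an all-inactive session is recovered as ~100% inactive", {
  cfg <- tiny_config(seed = 8)
  roster <- generate_roster(cfg)
  calib <- generate_calibration(roster, cfg)
  p <- roster[1, ]
  bands <- calib$bands[[p$player_id]]
  out <- generate_session_trace(
    p, list(session_type = "training", season_period = "regular",
            role = "starter", duration_min = 10,
            occupancy = c(1, 0, 0, 0, 0)),
    bands, cfg, seed = 99)
  force <- trace_to_force(out$trace, p$mass_kg)
  lab <- classify_epochs(force, bands)
  expect_gte(mean(lab == "inactive"), 0.99)
})

test_that("cohort observation counts mirror the study sizes exactly", {
  co <- generate_cohort(sim_config(seed = 1))
  tab <- table(co$ground_truth$session_type,
               co$ground_truth$season_period)
  expect_equal(tab["match", "regular"], 387)
  expect_equal(tab["match", "finals"], 75)
  expect_equal(tab["training", "regular"], 445)
  expect_equal(tab["training", "finals"], 113)
  # every observation has a manifest row
  expect_equal(nrow(co$manifest), nrow(co$ground_truth))
  expect_false(anyDuplicated(paste(co$manifest$session_id,
                                   co$manifest$player_id)) > 0)
})

test_that("cohort generation and trace materialization are deterministic", {
  cfg <- tiny_config(seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  row <- a$ground_truth[3, ]
  t1 <- materialize_trace(a, row$session_id, row$player_id)$trace
  t2 <- materialize_trace(b, row$session_id, row$player_id)$trace
  expect_identical(t1, t2)
})

test_that("planted band minutes conserve session duration", {
  co <- generate_cohort(sim_config(seed = 6))
  gt <- co$ground_truth
  epochs <- rowSums(gt[, band_cols])
  expect_equal(epochs * co$config$epoch_length / 60, gt$duration_min,
               tolerance = 1e-9)
})

test_that("a null starter shift leaves the match MD centered near zero", {
  cfg <- sim_config(seed = 31,
                    minutes_shift_finals = c(starter = 0,
                                             in_rotation = 0,
                                             out_rotation = 0))
  s <- cohort_summaries(generate_cohort(cfg))
  s <- s[s$session_type == "match" & s$role == "starter", ]
  md <- mean(s$minutes_played[s$season_period == "finals"]) -
    mean(s$minutes_played[s$season_period == "regular"])
  expect_lt(abs(md), 2.5)  # ~3 MC SDs of the null MD
})

test_that("cohort round-trips through plain-text files", {
  cfg <- tiny_config(seed = 13)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir,
               trace_keys = co$manifest[1, c("session_id", "player_id")])
  expect_true(all(file.exists(file.path(
    dir, c("roster.csv", "manifest.csv", "calibration.csv",
           "ground_truth.json")))))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(co$manifest))
  tr_file <- list.files(file.path(dir, "traces"), full.names = TRUE)
  expect_length(tr_file, 1)
  tr <- read_trace_csv(tr_file)
  orig <- materialize_trace(co, co$manifest$session_id[1],
                            co$manifest$player_id[1])$trace
  expect_equal(nrow(tr), nrow(orig))
  expect_equal(attr(tr, "sample_rate"), 100)
  expect_equal(tr$ax_g, orig$ax_g, tolerance = 1e-4)
})
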