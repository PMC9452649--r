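test_that("match window trimming keeps exactly the monitored span", {
  n <- 1200
  tr <- accel_trace(rnorm(n), rnorm(n), rnorm(n), 100)
  full <- match_window(tr, 0, max(tr$timestamp_s))
  expect_equal(nrow(full), n)
  half <- match_window(tr, 3, 8.99)
  expect_equal(nrow(half), sum(tr$timestamp_s >= 3 &
                                 tr$timestamp_s <= 8.99))
  expect_error(match_window(tr, 5, 60), "outside")
  expect_error(match_window(tr, 8, 3), "outside")
})

test_that("match roles follow the started flag and 10-minute rule", {
  expect_equal(as.character(assign_match_role(TRUE, 2)), "starter")
  expect_equal(as.character(assign_match_role(FALSE, 10.0)),
               "in_rotation")
  expect_equal(as.character(assign_match_role(FALSE, 9.9)),
               "out_rotation")
  expect_error(assign_match_role(FALSE, -1), "non-negative")
  # partition: every observation gets exactly one role
  set.seed(2)
  started <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  mins <- runif(200, 0, 40)
  r <- assign_match_role(started, mins)
  expect_false(anyNA(r))
  expect_equal(sum(table(r)), 200)
})

test_that("training role is the modal match role with involvement tie-break", {
  expect_equal(as.character(assign_training_role(
    c("starter", "starter", "in_rotation"))), "starter")
  expect_equal(as.character(assign_training_role(
    c("in_rotation", "out_rotation"))), "in_rotation")
  expect_equal(as.character(assign_training_role("out_rotation")),
               "out_rotation")
  expect_error(assign_training_role(character(0)), "no match roles")
})

test_that("session summaries conserve band minutes and percentages", {
  b <- bands_for_player(clean_model())
  force <- structure(c(rep(20, 60), rep(100, 30), rep(300, 20),
                       rep(470, 5), rep(600, 5)),
                     epoch_length = 1, player_id = "p1",
                     class = "force_series")
  lab <- classify_epochs(force, b)
  rec <- list(session_id = "s1", player_id = "p1",
              session_type = "match", season_period = "regular",
              team = "women", role = "starter", started = TRUE,
              minutes_played = 30)
  s <- summarize_session(rec, lab, force)
  mins <- unlist(s[paste0("min_", c("inactive", "light",
                                    "moderate_vigorous", "maximal",
                                    "supramaximal"))])
  expect_equal(unname(mins), c(60, 30, 20, 5, 5) / 60)
  expect_equal(sum(mins), s$monitored_duration)
  pct <- unlist(s[grep("^pct_", names(s))])
  expect_equal(sum(pct), 100, tolerance = 0.1)
  expect_equal(s$avf_net, mean(unclass(force)))
})

test_that("an all-inactive 90-min session summarizes as 90 min, 100%", {
  b <- bands_for_player(clean_model())
  force <- structure(rep(10, 90 * 60), epoch_length = 1,
                     player_id = "p1", class = "force_series")
  s <- summarize_session(list(session_id = "s", player_id = "p1"),
                         classify_epochs(force, b), force)
  expect_equal(s$min_inactive, 90)
  expect_equal(s$pct_inactive, 100)
})

test_that("summaries reject mismatched player keys", {
  b <- bands_for_player(clean_model())
  force <- structure(rep(10, 60), epoch_length = 1, player_id = "p1",
                     class = "force_series")
  expect_error(summarize_session(list(player_id = "p2"),
                                 classify_epochs(force, b), force),
               "belongs to")
})

test_that("weekly training load aggregates sessions into calendar weeks", {
  mk <- function(id, period, date, dur)
    data.frame(session_id = id, session_type = "training",
               season_period = period, date = as.Date(date),
               team = "women", monitored_duration = dur)
  summaries <- rbind(
    mk("t1", "regular", "2019-04-02", 90),
    mk("t2", "regular", "2019-04-09", 84),
    mk("t3", "regular", "2019-04-11", 100))
  w <- weekly_training_load(summaries)
  expect_equal(
    w$session_duration$median[
      w$session_duration$season_period == "regular"], 90)
  weekly <- sort(w$weekly_duration$median)
  # week 1: 90; week 2: 84 + 100 = 184 -> median of (90, 184)
  expect_equal(w$weekly_duration$median[
    w$weekly_duration$season_period == "regular"], (90 + 184) / 2)
  # no finals rows: period absent, not an error
  expect_false("finals" %in% w$session_duration$season_period)
})
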