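#' Trim a trace to the monitored match window
#'
#' Keeps the samples from the start of the first quarter to the end of
#' the final quarter (inclusive of stoppages, time-outs and
#' inter-quarter breaks); everything outside is dropped.
#'
#' @param trace an [accel_trace()].
#' @param start_s,end_s window bounds in trace time, seconds.
#' @return The trimmed `accel_trace`.
#' @export
match_window <- function(trace, start_s, end_s) {
  t_max <- max(trace$timestamp_s)
  if (start_s < 0 || end_s > t_max + 1e-9 || end_s <= start_s)
    stop_("match window [", start_s, ", ", end_s,
          "] outside trace extent [0, ", t_max, "]")
  keep <- trace$timestamp_s >= start_s & trace$timestamp_s <= end_s
  if (!any(keep)) stop_("empty match window")
  out <- trace[keep, , drop = FALSE]
  attributes(out)[c("sample_rate", "player_id", "session_id")] <-
    attributes(trace)[c("sample_rate", "player_id", "session_id")]
  class(out) <- class(trace)
  out
}

#' Assign a player's role for one match
#'
#' Starters are the players on court at tip-off. Bench players who play
#' ten or more minutes are in-rotation; the remaining bench players are
#' out-rotation.
#'
#' @param started logical, on court at the start (vectorized).
#' @param minutes_played minutes, >= 0.
#' @return Factor with levels starter / in_rotation / out_rotation.
#' @export
assign_match_role <- function(started, minutes_played) {
  if (any(minutes_played < 0, na.rm = TRUE))
    stop_("minutes_played must be non-negative")
  role <- ifelse(started, "starter",
                 ifelse(minutes_played >= 10, "in_rotation",
                        "out_rotation"))
  factor(role, levels = ROLE_LEVELS)
}

#' Assign a player's training role from their season of match roles
#'
#' The modal match role across the season; ties break toward the
#' higher-involvement role (starter over in-rotation over
#' out-rotation).
#'
#' @param match_roles character or factor vector of match roles.
#' @return Single factor level.
#' @export
assign_training_role <- function(match_roles) {
  match_roles <- as.character(match_roles)
  if (!length(match_roles))
    stop_("no match roles observed; training role undefined")
  counts <- vapply(ROLE_LEVELS, function(r) sum(match_roles == r),
                   numeric(1))
  factor(ROLE_LEVELS[which.max(counts)], levels = ROLE_LEVELS)
}

#' Summarize one player-session
#'
#' Collapses labeled epochs and the force series into the unit of
#' statistical analysis: session AvF_NET (N), impulse (kN·s), absolute
#' minutes and percent of monitored time in each of the five intensity
#' bands.
#'
#' @param record list or one-row data frame with `session_id`,
#'   `player_id`, `session_type`, `season_period`, `team`, `role`, and
#'   (for matches) `started`, `minutes_played`.
#' @param epochs factor of band labels from [classify_epochs()].
#' @param force the matching `force_series`.
#' @return One-row data frame of class `session_summary` layout.
#' @export
summarize_session <- function(record, epochs, force) {
  if (length(epochs) != length(force))
    stop_("epoch labels and force series differ in length")
  pid <- attr(force, "player_id")
  if (!is.na(pid) && !is.null(record$player_id) &&
      !is.na(record$player_id) && pid != record$player_id)
    stop_("force series belongs to player '", pid, "', record to '",
          record$player_id, "'")
  epl <- attr(force, "epoch_length") %||% 1
  monitored <- length(epochs) * epl / 60
  mins <- vapply(BAND_LEVELS, function(b) sum(epochs == b) * epl / 60,
                 numeric(1))
  dur_s <- length(force) * epl
  out <- data.frame(
    session_id = record$session_id %||% NA_character_,
    session_type = record$session_type %||% NA_character_,
    season_period = record$season_period %||% NA_character_,
    date = record$date %||% as.Date(NA),
    team = record$team %||% NA_character_,
    player_id = record$player_id %||% pid,
    role = as.character(record$role %||% NA_character_),
    started = record$started %||% NA,
    minutes_played = record$minutes_played %||% NA_real_,
    monitored_duration = monitored,
    avf_net = session_intensity(force),
    impulse = session_impulse(force, dur_s),
    stringsAsFactors = FALSE)
  m <- as.data.frame(as.list(setNames(mins, paste0("min_", BAND_LEVELS))))
  p <- as.data.frame(as.list(setNames(100 * mins / monitored,
                                      paste0("pct_", BAND_LEVELS))))
  cbind(out, m, p)
}

#' Training-load schedule summaries
#'
#' Median (Q1--Q3) of training session durations and of cumulative
#' weekly training durations, per season period. Weeks are calendar
#' weeks (Monday start).
#'
#' @param summaries session-summary frame (training rows are selected
#'   internally).
#' @return List with `session_duration` and `weekly_duration`, each a
#'   data frame of period, median, q1, q3 (empty periods are absent).
#' @export
weekly_training_load <- function(summaries) {
  tr <- summaries[summaries$session_type == "training", ]
  per_session <- unique(tr[, c("session_id", "season_period", "date",
                               "team", "monitored_duration")])
  qs <- function(x) {
    q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    data.frame(median = q[1], q1 = q[2], q3 = q[3])
  }
  by_period <- function(df, value) {
    out <- lapply(split(df[[value]], df$season_period), qs)
    periods <- names(out)
    cbind(data.frame(season_period = periods), do.call(rbind, out),
          row.names = NULL)
  }
  dates <- as.Date(per_session$date)
  per_session$week <- format(dates - (as.POSIXlt(dates)$wday + 6) %% 7,
                             "%Y-%m-%d")
  weekly <- aggregate(monitored_duration ~ team + week + season_period,
                      per_session, sum)
  list(session_duration = by_period(per_session, "monitored_duration"),
       weekly_duration = by_period(weekly, "monitored_duration"))
}
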