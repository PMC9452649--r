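# Session calendar for one cohort: trainings Tue/Thu (up to 2/week),
# matches Saturday, finals weeks following the longest regular season.
build_calendar_ <- function(config) {
  base <- as.Date("2019-04-01")  # a Monday
  teams <- names(config$n_players)
  reg_weeks <- max(vapply(teams, function(tm) {
    s <- config$sessions[[tm]]
    max(ceiling(s[["training_regular"]] / 2), s[["match_regular"]])
  }, numeric(1)))
  rows <- list()
  for (tm in teams) {
    s <- config$sessions[[tm]]
    for (period in c("regular", "finals")) {
      off <- if (period == "regular") 0 else reg_weeks
      n_tr <- s[[paste0("training_", period)]]
      n_ma <- s[[paste0("match_", period)]]
      if (n_tr > 0) {
        i <- seq_len(n_tr)
        wk <- ceiling(i / 2)
        dow <- ifelse(i %% 2 == 1, 1, 3)  # Tue, Thu
        rows[[length(rows) + 1]] <- data.frame(
          team = tm, session_type = "training", season_period = period,
          idx = i, date = base + (off + wk - 1) * 7 + dow,
          stringsAsFactors = FALSE)
      }
      if (n_ma > 0) {
        i <- seq_len(n_ma)
        rows[[length(rows) + 1]] <- data.frame(
          team = tm, session_type = "match", season_period = period,
          idx = i, date = base + (off + i - 1) * 7 + 5,  # Sat
          stringsAsFactors = FALSE)
      }
    }
  }
  cal <- do.call(rbind, rows)
  cal$session_id <- sprintf("%s_%s_%s_%02d", cal$team,
                            substr(cal$session_type, 1, 5),
                            substr(cal$season_period, 1, 3), cal$idx)
  cal
}

# Number of absentees per session so each (type, period) cell hits its
# observation target exactly. Returns an integer vector along sessions.
allocate_absences_ <- function(capacity, eligible, target) {
  total_capacity <- sum(capacity)
  absent_total <- total_capacity - target
  if (absent_total < 0)
    stop_("observation target ", target, " exceeds capacity ",
          total_capacity)
  n <- length(capacity)
  absent <- rep(absent_total %/% n, n)
  rem <- absent_total %% n
  if (rem > 0) {
    extra <- sample.int(n, rem)
    absent[extra] <- absent[extra] + 1
  }
  # shift overflow beyond the eligible pool to other sessions
  for (i in seq_len(n)) {
    over <- absent[i] - eligible[i]
    if (over > 0) {
      absent[i] <- eligible[i]
      room <- which(absent < eligible)
      for (j in room) {
        move <- min(over, eligible[j] - absent[j])
        absent[j] <- absent[j] + move
        over <- over - move
        if (over == 0) break
      }
      if (over > 0) stop_("cannot allocate attendance to hit target")
    }
  }
  absent
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces the full study scaffold: roster, per-player calibration
#' stages/models/bands, a dated session manifest whose attendance is
#' thinned to the configured observation totals (by default 387 regular
#' season and 75 finals match observations; 445 and 113 for training),
#' and per-observation ground truth: realized role, planted minutes
#' played (role mean + between-player intercept + finals shift + match
#' noise), realized band occupancy (logistic-normal jitter around the
#' role/period target) and the implied per-band epoch counts, session
#' AvF_NET and impulse. Raw traces are not stored; they are
#' reconstructed deterministically on demand with
#' [materialize_trace()] from per-observation seeds.
#'
#' @param config a [sim_config()].
#' @return A `courtload_cohort` list: `config`, `roster`,
#'   `calibration`, `manifest`, `ground_truth`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  roster <- generate_roster(config)
  calibration <- generate_calibration(roster, config)
  cal <- build_calendar_(config)

  with_seed_(config$seed + 2L, {
    # training session durations (whole minutes within the study range)
    cal$duration_min <- ifelse(
      cal$session_type == "match", config$match_duration,
      round(rnorm_trunc_(nrow(cal), config$training_duration, 6,
                         config$training_duration_range[1],
                         config$training_duration_range[2])))
    # per-player between-session playing-time intercepts
    mm <- config$minutes_model
    u <- rnorm(nrow(roster)) * vapply(
      roster$role_planted, function(r) mm[[r]][["between_sd"]],
      numeric(1))
    names(u) <- roster$player_id

    # attendance per (type, period) cell
    cal$n_absent <- 0L
    for (type in c("match", "training")) {
      for (period in c("regular", "finals")) {
        sel <- which(cal$session_type == type &
                       cal$season_period == period)
        if (!length(sel)) next
        capacity <- config$n_players[cal$team[sel]]
        eligible <- if (type == "match") {
          vapply(cal$team[sel], function(tm)
            sum(config$role_mix[[tm]][c("in_rotation", "out_rotation")]),
            numeric(1))
        } else capacity
        target <- config$observation_targets[[paste(type, period,
                                                    sep = "_")]]
        cal$n_absent[sel] <- allocate_absences_(capacity, eligible,
                                                target)
      }
    }

    mm_mean <- vapply(mm, `[[`, numeric(1), "mean")
    mm_wsd <- vapply(mm, `[[`, numeric(1), "within_sd")
    centers_mat <- t(vapply(roster$player_id, function(pid)
      band_centers(calibration$bands[[pid]]), numeric(5)))

    idx <- minutes <- vector("list", nrow(cal))
    started <- role <- vector("list", nrow(cal))
    team_rows <- split(seq_len(nrow(roster)), roster$team)
    for (k in seq_len(nrow(cal))) {
      ses <- cal[k, ]
      tr <- team_rows[[ses$team]]
      pool <- if (ses$session_type == "match")
        tr[roster$role_planted[tr] != "starter"] else tr
      absent <- if (ses$n_absent > 0)
        sample(pool, ses$n_absent) else integer(0)
      pres <- setdiff(tr, absent)
      n <- length(pres)
      idx[[k]] <- pres
      if (ses$session_type == "match") {
        pr <- roster$role_planted[pres]
        shift <- if (ses$season_period == "finals")
          config$minutes_shift_finals[pr] else 0
        # cap: 40 min regulation plus one overtime period
        mins <- pmin(pmax(mm_mean[pr] + shift + u[pres] +
                            rnorm(n) * mm_wsd[pr], 0), 45)
        minutes[[k]] <- round(mins, 1)
        started[[k]] <- pr == "starter"
        role[[k]] <- as.character(assign_match_role(started[[k]], mins))
      } else {
        minutes[[k]] <- rep(NA_real_, n)
        started[[k]] <- rep(NA, n)
        role[[k]] <- roster$role_planted[pres]
      }
    }

    n_per <- lengths(idx)
    ses_of <- rep(seq_len(nrow(cal)), n_per)
    pidx <- unlist(idx, use.names = FALSE)
    gt <- data.frame(
      session_id = cal$session_id[ses_of],
      session_type = cal$session_type[ses_of],
      season_period = cal$season_period[ses_of],
      date = cal$date[ses_of], team = cal$team[ses_of],
      player_id = roster$player_id[pidx],
      started = unlist(started, use.names = FALSE),
      minutes_played = unlist(minutes, use.names = FALSE),
      duration_min = cal$duration_min[ses_of],
      role = unlist(role, use.names = FALSE),
      stringsAsFactors = FALSE)

    # occupancy: one vectorized logistic-normal draw over observations
    key <- paste(gt$session_type, gt$role, gt$season_period)
    targets <- do.call(rbind, lapply(strsplit(unique(key), " "),
                                     function(p)
                                       occupancy_target_(config, p[1],
                                                         p[2], p[3])))
    rownames(targets) <- unique(key)
    occ <- targets[key, , drop = FALSE] *
      exp(matrix(rnorm(nrow(gt) * 5, 0, config$occupancy_jitter_sd),
                 ncol = 5))
    occ <- occ / rowSums(occ)
    n_epochs <- round(gt$duration_min * 60 / config$epoch_length)
    band_ep <- floor(occ * n_epochs)
    short <- n_epochs - rowSums(band_ep)
    frac <- occ * n_epochs - band_ep
    rk <- t(apply(-frac, 1, rank, ties.method = "first"))
    band_ep <- band_ep + (rk <= short)  # largest-remainder completion
    gt$avf_net <- rowSums(band_ep / n_epochs *
                            centers_mat[pidx, , drop = FALSE])
    gt$impulse <- gt$avf_net * gt$duration_min * 60 / 1000
    colnames(band_ep) <- paste0("epochs_", BAND_LEVELS)
    gt <- cbind(gt, band_ep)
    rownames(gt) <- NULL
    gt$trace_seed <- derive_seeds_(config$seed + 3L, nrow(gt))

    manifest <- gt[, c("session_id", "session_type", "season_period",
                       "date", "player_id", "started", "minutes_played")]
    structure(list(config = config, roster = roster,
                   calibration = calibration, manifest = manifest,
                   ground_truth = gt),
              class = "courtload_cohort")
  })
}

#' @export
print.courtload_cohort <- function(x, ...) {
  tab <- table(x$ground_truth$session_type, x$ground_truth$season_period)
  cat("Synthetic basketball cohort:", nrow(x$roster), "players,",
      length(unique(x$ground_truth$session_id)), "sessions,",
      nrow(x$ground_truth), "player-session observations\n")
  print(tab)
  invisible(x)
}

#' Reconstruct the raw trace for one cohort observation
#'
#' Deterministically rebuilds the 100 Hz triaxial trace for a
#' player-session from its stored seed and realized band occupancy.
#' The bout schedule's per-band epoch counts equal the ground-truth
#' `epochs_*` columns exactly.
#'
#' @param cohort a [generate_cohort()] result.
#' @param session_id,player_id observation keys.
#' @return List with `trace` and `ground_truth` (as in
#'   [generate_session_trace()]).
#' @export
materialize_trace <- function(cohort, session_id, player_id) {
  gt <- cohort$ground_truth
  i <- which(gt$session_id == session_id & gt$player_id == player_id)
  if (length(i) != 1)
    stop_("no unique observation for session '", session_id,
          "', player '", player_id, "'")
  row <- gt[i, ]
  ep <- as.numeric(row[paste0("epochs_", BAND_LEVELS)])
  player <- cohort$roster[cohort$roster$player_id == player_id, ]
  bands <- cohort$calibration$bands[[player_id]]
  spec <- list(session_type = row$session_type,
               season_period = row$season_period, role = row$role,
               duration_min = row$duration_min,
               occupancy = ep / sum(ep), session_id = session_id)
  generate_session_trace(player, spec, bands, cohort$config,
                         seed = row$trace_seed)
}

#' Session summaries implied by cohort ground truth
#'
#' Assembles the analysis frame (one row per player-session with
#' AvF_NET, impulse, absolute and relative band minutes, minutes
#' played, role, period, team) directly from the planted ground truth,
#' bypassing trace synthesis. This is the cohort-scale route used for
#' statistical simulation; the trace route ([run_pipeline()]) recovers
#' the same summaries to within the banding tolerance.
#'
#' @param cohort a [generate_cohort()] result.
#' @return Data frame of session summaries.
#' @export
cohort_summaries <- function(cohort) {
  gt <- cohort$ground_truth
  epl <- cohort$config$epoch_length
  out <- gt[, c("session_id", "session_type", "season_period", "date",
                "team", "player_id", "role", "started",
                "minutes_played", "duration_min", "avf_net", "impulse")]
  names(out)[names(out) == "duration_min"] <- "monitored_duration"
  ep <- as.matrix(gt[, paste0("epochs_", BAND_LEVELS)])
  mins <- ep * epl / 60
  pct <- 100 * mins / out$monitored_duration
  colnames(mins) <- paste0("min_", BAND_LEVELS)
  colnames(pct) <- paste0("pct_", BAND_LEVELS)
  cbind(out, mins, pct)
}

#' Write a cohort to plain-text files
#'
#' Writes `roster.csv`, `manifest.csv`, `calibration.csv` (stage
#' records), and `ground_truth.json` under `dir`. Optionally writes
#' trace CSVs (`traces/<session>_<player>.csv` with columns
#' `timestamp_s, ax_g, ay_g, az_g`) for selected observations; traces
#' are large, so none are written by default.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param trace_keys optional data frame with `session_id`, `player_id`
#'   rows to materialize as CSV.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, trace_keys = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$roster[, c("player_id", "team", "sex", "mass_kg",
                              "vo2max_mlkgmin")],
            file.path(dir, "roster.csv"), row.names = FALSE)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  write.csv(cohort$calibration$stages[, c("player_id", "speed_kmh",
                                          "avf_net_n")],
            file.path(dir, "calibration.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(trace_keys)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_len(nrow(trace_keys))) {
      tr <- materialize_trace(cohort, trace_keys$session_id[i],
                              trace_keys$player_id[i])$trace
      write.csv(format(as.data.frame(tr), digits = 6),
                file.path(tdir, paste0(trace_keys$session_id[i], "_",
                                       trace_keys$player_id[i], ".csv")),
                row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
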