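#' Read a trace CSV
#'
#' Reads `timestamp_s, ax_g, ay_g, az_g` columns written by
#' [write_cohort()] (or any device export in that layout) into an
#' [accel_trace()]. The sample rate is inferred from the timestamp
#' spacing unless given.
#'
#' @param path CSV path.
#' @param sample_rate Hz; inferred from timestamps when `NULL`.
#' @param player_id,session_id identifiers.
#' @return An `accel_trace`.
#' @export
read_trace_csv <- function(path, sample_rate = NULL,
                           player_id = NA_character_,
                           session_id = NA_character_) {
  df <- read.csv(path)
  need <- c("timestamp_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stop_("trace file must have columns ", paste(need, collapse = ", "))
  if (is.null(sample_rate))
    sample_rate <- round(1 / median(diff(df$timestamp_s)))
  accel_trace(df$ax_g, df$ay_g, df$az_g, sample_rate,
              player_id = player_id, session_id = session_id)
}

#' Validate pipeline inputs
#'
#' Structural checks on a cohort (or a list with `roster`, `manifest`,
#' `config` in the same shapes): positive body masses, unique
#' (session, player) keys, manifest players known to the roster,
#' sample rate comfortably above twice the filter's upper cut-off.
#' Fatal problems and warnings are distinguished by severity; nothing
#' is raised.
#'
#' @param x a `courtload_cohort` or compatible list.
#' @param high upper filter cut-off the data will be filtered with, Hz.
#' @return Data frame `severity, check, message`; zero rows when clean.
#' @export
validate_inputs <- function(x, high = 15) {
  rep <- list()
  add <- function(severity, check, message)
    rep[[length(rep) + 1]] <<- data.frame(
      severity = severity, check = check, message = message,
      stringsAsFactors = FALSE)
  roster <- x$roster; manifest <- x$manifest; config <- x$config
  if (is.null(roster) || is.null(manifest)) {
    add("error", "schema", "roster and manifest are required")
  } else {
    if (any(roster$mass_kg <= 0, na.rm = TRUE))
      add("error", "mass", "non-positive body mass in roster")
    keys <- paste(manifest$session_id, manifest$player_id)
    if (anyDuplicated(keys))
      add("error", "keys", paste("duplicated (session_id, player_id):",
                                 keys[duplicated(keys)][1]))
    unknown <- setdiff(manifest$player_id, roster$player_id)
    if (length(unknown))
      add("error", "players",
          paste("manifest references unknown players:",
                paste(unknown, collapse = ", ")))
    neg <- manifest$minutes_played < 0
    if (any(neg, na.rm = TRUE))
      add("error", "minutes", "negative minutes_played in manifest")
  }
  if (!is.null(config)) {
    fs <- config$sample_rate
    if (fs <= 2 * high)
      add("error", "nyquist",
          sprintf("sample rate %g Hz violates Nyquist for %g Hz", fs,
                  high))
    else if (fs < 4 * high)
      add("warning", "nyquist",
          sprintf("sample rate %g Hz leaves little margin over the %g Hz cut-off",
                  fs, high))
  }
  if (!length(rep))
    return(data.frame(severity = character(0), check = character(0),
                      message = character(0)))
  do.call(rbind, rep)
}

# Season training roles: modal match role per player, from match
# observations in the manifest-derived summaries.
training_roles_ <- function(match_frame) {
  roles <- lapply(split(match_frame$role, match_frame$player_id),
                  assign_training_role)
  vapply(roles, as.character, character(1))
}

#' Run the trace-level pipeline over cohort observations
#'
#' For each selected player-session: materialize the raw trace, filter
#' and convert it to an epoch force series ([trace_to_force()]),
#' classify epochs against the player's calibration bands (refit from
#' the cohort's stage records) and summarize the session. Match roles
#' come from the manifest (started flag and league minutes); training
#' roles are each player's modal match role across the season.
#'
#' @param cohort a [generate_cohort()] result.
#' @param observations data frame with `session_id`, `player_id` rows
#'   to process (default: the full manifest; note each 90-min trace
#'   takes a few seconds).
#' @param low,high,order filter settings.
#' @param epoch_length epoch for banding, seconds.
#' @return Data frame of session summaries (one row per observation).
#' @export
run_pipeline <- function(cohort, observations = cohort$manifest,
                         low = 0.1, high = 15, order = 4,
                         epoch_length = cohort$config$epoch_length) {
  report <- validate_inputs(cohort, high = high)
  if (any(report$severity == "error"))
    stop_("invalid inputs: ",
          paste(report$message[report$severity == "error"],
                collapse = "; "))
  # refit calibrations from stage records rather than trusting the
  # generator's models
  stages <- cohort$calibration$stages
  bands <- lapply(split(stages, stages$player_id), function(st) {
    m <- fit_calibration(st$avf_net_n, st$vo2_mlkgmin,
                         vo2_rest = cohort$config$vo2_rest,
                         vo2_max = max(st$vo2_mlkgmin),
                         player_id = st$player_id[1])
    bands_for_player(m)
  })

  man <- cohort$manifest
  match_man <- man[man$session_type == "match", ]
  match_man$role <- assign_match_role(match_man$started,
                                      match_man$minutes_played)
  train_role <- training_roles_(match_man)

  out <- vector("list", nrow(observations))
  for (i in seq_len(nrow(observations))) {
    sid <- observations$session_id[i]
    pid <- observations$player_id[i]
    j <- which(man$session_id == sid & man$player_id == pid)
    if (length(j) != 1)
      stop_("observation (", sid, ", ", pid, ") not in manifest")
    rec <- man[j, ]
    rec$team <- cohort$roster$team[cohort$roster$player_id == pid]
    rec$role <- if (rec$session_type == "match")
      as.character(assign_match_role(rec$started, rec$minutes_played))
    else unname(train_role[pid])
    tr <- materialize_trace(cohort, sid, pid)$trace
    mass <- cohort$roster$mass_kg[cohort$roster$player_id == pid]
    force <- trace_to_force(tr, mass, low = low, high = high,
                            order = order,
                            epoch_length = epoch_length)
    labels <- classify_epochs(force, bands[[pid]])
    out[[i]] <- summarize_session(rec, labels, force)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

DEMAND_VARIABLES <- c("minutes_played", "avf_net", "impulse",
                      paste0("min_", BAND_LEVELS),
                      paste0("pct_", BAND_LEVELS))

OFFSET_VARIABLES <- c("minutes_played", "min_maximal",
                      "min_supramaximal", "pct_maximal",
                      "pct_supramaximal")

#' Period comparison of demand variables with the full decision tree
#'
#' For each requested variable: log-transform (offset +1 for variables
#' that can contain zeros), run the [interaction_decision_tree()], and
#' compute regular-vs-finals contrasts for the groups the chosen
#' branch dictates — per role-by-team cell after a 3-way interaction,
#' per role after a period-by-role interaction, all observations
#' together for a main effect (none for a reported-only period-by-team
#' interaction). Each contrast carries a cluster-stratified bootstrap
#' mean difference on original units, a Bonferroni-adjusted p from the
#' follow-up model family, and log-scale Cohen's d.
#'
#' @param summaries analysis frame (e.g. [cohort_summaries()] or
#'   [run_pipeline()] output); match and training sessions should be
#'   analyzed separately.
#' @param variables response columns to analyze.
#' @param reps bootstrap replicates per contrast.
#' @param seed RNG seed.
#' @param alpha significance threshold.
#' @return Named list per variable: `tree` (decision-tree result) and
#'   `comparisons` (data frame of contrasts), plus a `normality` frame.
#' @export
analyze_demands <- function(summaries,
                            variables = intersect(DEMAND_VARIABLES,
                                                  names(summaries)),
                            reps = 1000, seed = 1, alpha = 0.05) {
  summaries <- summaries[!is.na(summaries$role), ]
  norm <- normality_check(summaries[, variables, drop = FALSE])
  seeds <- derive_seeds_(seed, length(variables))
  results <- setNames(vector("list", length(variables)), variables)
  for (vi in seq_along(variables)) {
    v <- variables[vi]
    frame <- summaries[!is.na(summaries[[v]]), ]
    frame <- log_transform(frame, v, OFFSET_VARIABLES)
    resp <- paste0(v, "_log")
    tree <- interaction_decision_tree(frame, resp, alpha = alpha)
    groups <- switch(
      tree$branch,
      three_way_interaction = split(
        frame, list(frame$role, frame$team), drop = TRUE),
      period_role_interaction = split(frame, frame$role, drop = TRUE),
      period_main_effect = list(all = frame),
      period_team_interaction_reported_only = list())
    pvals <- if (!is.null(tree$follow_up)) tree$follow_up$p_period
    else if (tree$branch == "period_main_effect")
      lmm_term_p_(tree$models$reduced, "season_period")
    comps <- NULL
    if (length(groups)) {
      padj <- bonferroni_adjust(pvals)
      comps <- do.call(rbind, lapply(seq_along(groups), function(g) {
        sub <- groups[[g]]
        a <- sub[sub$season_period == "regular", ]
        b <- sub[sub$season_period == "finals", ]
        if (!nrow(a) || !nrow(b))
          return(NULL)
        bmd <- bootstrap_mean_difference(
          a[[v]], b[[v]], reps = reps, seed = seeds[vi] + g,
          subjects_a = a$player_id, subjects_b = b$player_id,
          label = paste0(v, " [", names(groups)[g], "]"))
        d <- cohens_d_log(a[[resp]], b[[resp]])
        data.frame(variable = v, group = names(groups)[g],
                   md = bmd$md, ci_low = bmd$ci_low,
                   ci_high = bmd$ci_high,
                   p_adjusted = padj[min(g, length(padj))],
                   d = d$d, d_label = d$label,
                   stringsAsFactors = FALSE)
      }))
    }
    results[[v]] <- list(tree = tree, comparisons = comps)
  }
  results$normality <- norm
  results
}
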