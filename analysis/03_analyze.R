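#!/usr/bin/env Rscript
# Stage 3 — statistical comparison of regular season vs. finals.
#
# Runs the full inferential pipeline on the simulated cohort's session
# summaries, separately for matches and training sessions: Shapiro-Wilk
# screen, ln(y) / ln(y+1) transforms, the period x role x team mixed
# models with the interaction decision tree, Bonferroni-adjusted
# follow-ups, cluster-stratified bootstrap mean differences and
# log-scale Cohen's d, plus median (Q1-Q3) demand tables and the
# weekly training-load summary. Writes compact tables under results/.

suppressMessages(library(courtload))

cohort <- generate_cohort(sim_config(seed = 2019))
s <- cohort_summaries(cohort)
dir.create("results", showWarnings = FALSE)

vars_match <- c("minutes_played", "avf_net", "impulse",
                paste0("min_", c("inactive", "light",
                                 "moderate_vigorous", "maximal",
                                 "supramaximal")),
                paste0("pct_", c("inactive", "light",
                                 "moderate_vigorous", "maximal",
                                 "supramaximal")))
vars_train <- setdiff(vars_match, "minutes_played")

run_block <- function(frame, vars, label, seed) {
  res <- analyze_demands(frame, vars, reps = 1000, seed = seed)
  logs <- do.call(rbind, lapply(vars, function(v)
    cbind(variable = v, res[[v]]$tree$log,
          branch = res[[v]]$tree$branch)))
  comps <- do.call(rbind, lapply(vars, function(v)
    res[[v]]$comparisons))
  write.csv(logs, sprintf("results/%s_decision_log.csv", label),
            row.names = FALSE)
  if (!is.null(comps))
    write.csv(comps, sprintf("results/%s_comparisons.csv", label),
              row.names = FALSE)
  write.csv(res$normality, sprintf("results/%s_normality.csv", label),
            row.names = FALSE)
  tab <- report_tables(frame, vars)
  write.csv(tab, sprintf("results/%s_table.csv", label),
            row.names = FALSE)
  cat("\n==", label, "==\n")
  for (v in vars) {
    cat(sprintf("%-22s -> %s\n", v, res[[v]]$tree$branch))
  }
  if (!is.null(comps)) {
    sig <- comps[comps$p_adjusted <= 0.05, ]
    if (nrow(sig)) {
      cat("significant period contrasts (Bonferroni p <= 0.05):\n")
      print(sig[, c("variable", "group", "md", "ci_low", "ci_high",
                    "p_adjusted", "d_label")], row.names = FALSE)
    }
  }
  invisible(res)
}

m <- s[s$session_type == "match", ]
run_block(m, vars_match, "match", seed = 101)

tr <- s[s$session_type == "training", ]
run_block(tr, vars_train, "training", seed = 202)

w <- weekly_training_load(s)
write.csv(merge(w$session_duration, w$weekly_duration,
                by = "season_period",
                suffixes = c("_session", "_weekly")),
          "results/weekly_training_load.csv", row.names = FALSE)
cat("\nTraining durations (median min): regular",
    w$session_duration$median[
      w$session_duration$season_period == "regular"],
    "finals", w$session_duration$median[
      w$session_duration$season_period == "finals"], "\n")
cat("Wrote results/{match,training}_{decision_log,comparisons,normality,table}.csv",
    "and results/weekly_training_load.csv\n")
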