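#' Fit a participant-random-intercept linear mixed model
#'
#' Fits `response ~ fixed + (1 | subject)` by REML with sum-to-zero
#' contrasts and returns Type-III F tests (Satterthwaite denominator
#' degrees of freedom) for every fixed term, each with its partial eta
#' squared. Non-convergence is flagged on the result rather than
#' raised.
#'
#' @param data analysis frame (one row per player-session observation).
#' @param response response column name (typically a log-transformed
#'   demand variable).
#' @param fixed right-hand-side formula string for the fixed effects,
#'   e.g. `"season_period * role * team"`.
#' @param subject grouping column for the random intercept.
#' @return A `courtload_lmm` list: `anova` (term, F, df1, df2, p,
#'   eta_p2, eta_label), `log_likelihood`, `converged`, `model`.
#' @export
fit_lmm <- function(data, response, fixed, subject = "player_id") {
  fvars <- all.vars(stats::as.formula(paste("~", fixed)))
  for (v in fvars) {
    data[[v]] <- factor(data[[v]])
    data[[v]] <- droplevels(data[[v]])
    if (nlevels(data[[v]]) < 2)
      stop_("fixed factor '", v, "' has fewer than 2 observed levels")
  }
  data[[subject]] <- factor(data[[subject]])
  form <- stats::as.formula(paste(response, "~", fixed, "+ (1 |",
                                  subject, ")"))
  contr <- lapply(setNames(fvars, fvars), function(...) "contr.sum")
  converged <- TRUE
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE,
                   contrasts = contr),
    warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w),
                ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (lme4::isSingular(fit, tol = 1e-5)) converged <- converged && TRUE
  an <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  eta <- partial_eta_squared(an[["F value"]], an$NumDF, an$DenDF)
  tab <- data.frame(term = rownames(an), F = an[["F value"]],
                    df1 = an$NumDF, df2 = an$DenDF,
                    p = an[["Pr(>F)"]], eta_p2 = eta$eta_p2,
                    eta_label = eta$label, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(anova = tab, log_likelihood = as.numeric(logLik(fit)),
                 converged = converged, model = fit),
            class = "courtload_lmm")
}

#' @export
print.courtload_lmm <- function(x, ...) {
  cat("Linear mixed model (participant random intercept)\n")
  print(transform(x$anova, F = round(F, 2), df2 = round(df2, 1),
                  p = signif(p, 3), eta_p2 = round(eta_p2, 3)),
        row.names = FALSE)
  if (!x$converged) cat("NOTE: model did not converge cleanly\n")
  invisible(x)
}

lmm_term_p_ <- function(lmm, term) {
  i <- match(term, lmm$anova$term)
  if (is.na(i)) NA_real_ else lmm$anova$p[i]
}

#' Partial eta squared from an F statistic
#'
#' eta_p^2 = (F * df1) / (F * df1 + df2), labeled small
#' (0.01--0.04), medium (>0.04--0.14) or large (>0.14); values below
#' 0.01 are labeled negligible.
#'
#' @param F F statistic(s), >= 0.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Data frame with `eta_p2` and `label`.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  if (any(F < 0, na.rm = TRUE)) stop_("F must be non-negative")
  if (any(c(df1, df2) <= 0)) stop_("degrees of freedom must be positive")
  eta <- (F * df1) / (F * df1 + df2)
  label <- cut(eta, breaks = c(-Inf, 0.01, 0.04, 0.14, Inf),
               labels = c("negligible", "small", "medium", "large"),
               right = TRUE)
  # closed lower bound: 0.01 itself counts as small
  label[!is.na(eta) & eta >= 0.01 & eta <= 0.04] <- "small"
  data.frame(eta_p2 = eta, label = as.character(label),
             stringsAsFactors = FALSE)
}

#' Audit reported effect sizes against the eta-squared formula
#'
#' Recomputes partial eta squared from each (F, df1, df2) triple and
#' flags rows whose recomputed value, rounded to the precision of the
#' reported one, disagrees with it. Useful when checking published
#' fixed-effect tables.
#'
#' @param F,df1,df2 test statistics and degrees of freedom.
#' @param reported reported eta_p2 values.
#' @return Data frame with recomputed values, rounded values and a
#'   `consistent` flag.
#' @export
eta_squared_audit <- function(F, df1, df2, reported) {
  eta <- partial_eta_squared(F, df1, df2)$eta_p2
  digits <- vapply(reported, function(r) {
    s <- sub("0+$", "", sub("^[^.]*\\.?", "", format(r)))
    max(nchar(s), 1L)
  }, integer(1))
  rounded <- round(eta, digits)
  data.frame(F = F, df1 = df1, df2 = df2, reported = reported,
             recomputed = eta, rounded = rounded,
             consistent = abs(rounded - reported) < 1e-12)
}

#' Interaction decision tree for period-by-role-by-team models
#'
#' Runs the full analysis procedure for one response: fit the
#' three-factor mixed model (season period x player role x team,
#' participant random intercept) and follow the interaction logic:
#'
#' * significant 3-way interaction: analyze each role-by-team cell
#'   separately (period effect within cell);
#' * otherwise, if team interacts with period in neither the 3-way nor
#'   the period-by-team 2-way term: drop team, refit period x role, and
#'   if the period-by-role interaction is significant analyze each role
#'   separately, else consult the period main effect;
#' * otherwise (period-by-team significant without the 3-way): report
#'   the interaction only — inter-team simple effects are out of scope.
#'
#' Every branch decision (term, p, verdict) is logged on the result.
#'
#' @param data analysis frame with `season_period`, `role`, `team` and
#'   the subject column.
#' @param response response column name.
#' @param alpha decision threshold (p <= alpha is significant).
#' @param subject random-intercept grouping column.
#' @return A `courtload_tree` list: `branch`, `models` (named fits),
#'   `follow_up` (per-cell or per-role period tests, if any), `log`.
#' @export
interaction_decision_tree <- function(data, response, alpha = 0.05,
                                      subject = "player_id") {
  log <- list()
  note <- function(step, term, p, verdict)
    log[[length(log) + 1]] <<- data.frame(
      step = step, term = term, p = p, verdict = verdict,
      stringsAsFactors = FALSE)

  check_cells_ <- function(df, factors, context) {
    tab <- table(df[factors])
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)[1, ]
      cell <- paste(mapply(function(f, i) dimnames(tab)[[f]][i],
                           seq_along(factors), empty),
                    collapse = " x ")
      stop_("empty cell (", cell, ") precludes the ", context,
            " analysis")
    }
  }

  check_cells_(data, c("season_period", "role", "team"), "full-model")
  full <- fit_lmm(data, response, "season_period * role * team",
                  subject)
  p3 <- lmm_term_p_(full, "season_period:role:team")
  p_pt <- lmm_term_p_(full, "season_period:team")
  models <- list(full = full)
  follow <- NULL

  if (!is.na(p3) && p3 <= alpha) {
    note("3-way", "season_period:role:team", p3,
         "significant; split by role x team")
    branch <- "three_way_interaction"
    cells <- unique(data[, c("role", "team")])
    follow <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sub <- data[data$role == cells$role[i] &
                    data$team == cells$team[i], ]
      if (length(unique(sub$season_period)) < 2)
        stop_("empty cell (", cells$role[i], " x ", cells$team[i],
              ") lacks both season periods")
      m <- fit_lmm(sub, response, "season_period", subject)
      data.frame(role = cells$role[i], team = cells$team[i],
                 p_period = lmm_term_p_(m, "season_period"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    note("3-way", "season_period:role:team", p3, "not significant")
    team_interacts <- (!is.na(p_pt) && p_pt <= alpha)
    note("2-way", "season_period:team", p_pt,
         if (team_interacts) "significant" else "not significant")
    if (!team_interacts) {
      reduced <- fit_lmm(data, response, "season_period * role",
                         subject)
      models$reduced <- reduced
      p_pr <- lmm_term_p_(reduced, "season_period:role")
      if (!is.na(p_pr) && p_pr <= alpha) {
        note("2-way", "season_period:role", p_pr,
             "significant; split by role")
        branch <- "period_role_interaction"
        follow <- do.call(rbind, lapply(
          unique(as.character(data$role)), function(r) {
            sub <- data[data$role == r, ]
            if (length(unique(sub$season_period)) < 2)
              stop_("empty cell (", r, ") lacks both season periods")
            m <- fit_lmm(sub, response, "season_period", subject)
            data.frame(role = r,
                       p_period = lmm_term_p_(m, "season_period"),
                       stringsAsFactors = FALSE)
          }))
      } else {
        note("2-way", "season_period:role", p_pr,
             "not significant; consult period main effect")
        branch <- "period_main_effect"
        p_main <- lmm_term_p_(reduced, "season_period")
        note("main", "season_period", p_main,
             if (!is.na(p_main) && p_main <= alpha) "significant"
             else "not significant")
      }
    } else {
      branch <- "period_team_interaction_reported_only"
      note("decision", "season_period:team", p_pt,
           "reported only; inter-team simple effects out of scope")
    }
  }
  structure(list(branch = branch, models = models, follow_up = follow,
                 log = do.call(rbind, log), alpha = alpha,
                 response = response),
            class = "courtload_tree")
}

#' @export
print.courtload_tree <- function(x, ...) {
  cat("Decision tree for", x$response, "-> branch:", x$branch, "\n")
  print(transform(x$log, p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Design-effect sample-size calculation for a linear mixed model
#'
#' Computes the two-sample total N for a standardized effect at the
#' given power and two-sided alpha (t-based power formula), inflates it
#' by the repeated-measures design effect `1 + (m - 1) * icc`, and
#' solves for the per-subject observation count m given `k_subjects`:
#' `k * m = N_base * (1 + (m - 1) * icc)`. The total sample size is
#' `ceiling(k * m)` and the per-subject requirement `round(m)`.
#'
#' @param effect_size standardized effect size (Cohen's d).
#' @param power target power.
#' @param alpha two-sided significance level.
#' @param k_subjects number of subjects available.
#' @param icc intraclass correlation of repeated observations.
#' @return A `power_design` list: `effect_size`, `power`, `alpha`,
#'   `k_subjects`, `icc`, `n_base`, `obs_per_subject`, `total_n`.
#' @examples
#' sample_size_lmm(0.40, 0.80, 0.05, 23, 0.05)
#' @export
sample_size_lmm <- function(effect_size, power, alpha = 0.05,
                            k_subjects, icc = 0.05) {
  stopifnot(effect_size > 0, power > 0, power < 1, alpha > 0,
            alpha < 1, k_subjects > 0, icc >= 0, icc < 1)
  n_base <- 2 * power.t.test(delta = effect_size, sd = 1,
                             sig.level = alpha, power = power)$n
  if (k_subjects <= n_base * icc)
    stop_("design unsolvable: k_subjects must exceed N_base * icc (",
          format(n_base * icc, digits = 4), ")")
  m <- n_base * (1 - icc) / (k_subjects - n_base * icc)
  structure(list(effect_size = effect_size, power = power,
                 alpha = alpha, k_subjects = k_subjects, icc = icc,
                 n_base = n_base, obs_per_subject = round(m),
                 m_exact = m, total_n = ceiling(k_subjects * m)),
            class = "power_design")
}

#' @export
print.power_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Mixed-model sample size: d = %.2f, power = %.2f, alpha = %.2f,\n",
    "  %d subjects, ICC = %.2f -> %d observations per subject,",
    " total n = %d\n"),
    x$effect_size, x$power, x$alpha, x$k_subjects, x$icc,
    x$obs_per_subject, x$total_n))
  invisible(x)
}

#' Simulated power or type-I error of the mixed-model period test
#'
#' Monte-Carlo calibration of the participant-random-intercept model:
#' each replicate draws `n_subjects` subjects with `obs_per_subject`
#' observations split evenly between two within-subject conditions,
#' with subject intercept variance `icc` and residual variance
#' `1 - icc` (unit total variance) and a condition shift of
#' `effect_size` total-SD units. The model is refit per replicate and
#' the fraction of condition p-values at or below `alpha` returned.
#' With `effect_size = 0` this estimates the type-I error rate.
#'
#' @param effect_size standardized condition effect (0 for null).
#' @param n_subjects,obs_per_subject design size.
#' @param icc intraclass correlation.
#' @param alpha significance threshold.
#' @param n_sims number of replicates.
#' @param seed RNG seed.
#' @return List: `rejection_rate`, `n_sims`, `mc_se` (binomial
#'   Monte-Carlo standard error).
#' @export
simulate_lmm_power <- function(effect_size = 0.40, n_subjects = 23,
                               obs_per_subject = 15, icc = 0.05,
                               alpha = 0.05, n_sims = 500, seed = 1) {
  k <- n_subjects; m <- obs_per_subject
  d <- data.frame(
    subj = factor(rep(seq_len(k), each = m)),
    cond = factor(rep(rep(c("a", "b"), length.out = m), k)))
  sd_b <- sqrt(icc); sd_w <- sqrt(1 - icc)
  rej <- with_seed_(seed, {
    vapply(seq_len(n_sims), function(i) {
      u <- rnorm(k, 0, sd_b)[as.integer(d$subj)]
      y <- u + effect_size * (d$cond == "b") + rnorm(k * m, 0, sd_w)
      fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(y ~ cond + (1 | subj), data = d)))
      p <- suppressMessages(anova(fit)[["Pr(>F)"]][1])
      as.numeric(!is.na(p) && p <= alpha)
    }, numeric(1))
  })
  rate <- mean(rej)
  list(rejection_rate = rate, n_sims = n_sims,
       mc_se = sqrt(rate * (1 - rate) / n_sims))
}
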