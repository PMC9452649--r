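test_that("Shapiro-Wilk screen separates normal from skewed samples", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    normality_check(rnorm(500))$p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  set.seed(1)
  expect_lt(normality_check(rlnorm(500, 0, 1))$p, 0.05)
  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("log transform applies the +1 offset only where declared", {
  d <- data.frame(minutes_played = c(0, exp(1) - 1, 5),
                  avf_net = c(100, 200, 300),
                  pct_light = c(0, 1, 2))
  out <- log_transform(d, c("minutes_played", "avf_net"))
  expect_equal(out$minutes_played_log[1], 0)
  expect_equal(out$minutes_played_log[2], 1)
  expect_equal(out$avf_net_log, log(d$avf_net))
  expect_equal(unname(attr(out, "log_transform")["minutes_played"]), 1)
  expect_error(log_transform(d, "pct_light"),
               "pct_light")
})

test_that("partial eta squared reproduces worked values and bins", {
  r <- partial_eta_squared(c(3.25, 5.22, 0), c(2, 2, 2),
                           c(342, 342, 342))
  expect_equal(round(r$eta_p2[1], 2), 0.02)
  expect_equal(round(r$eta_p2[2], 2), 0.03)
  expect_equal(r$eta_p2[3], 0)
  expect_equal(r$label[1:2], c("small", "small"))
  expect_equal(partial_eta_squared(50, 2, 100)$label, "large")
  expect_equal(partial_eta_squared(0.2, 1, 400)$label, "negligible")
})

test_that("eta-squared audit flags inconsistent published pairs", {
  audit <- eta_squared_audit(F = c(3.25, 7.74), df1 = c(2, 2),
                             df2 = c(342, 462),
                             reported = c(0.02, 0.05))
  expect_true(audit$consistent[1])
  expect_false(audit$consistent[2])  # formula gives 0.03, not 0.05
})

test_that("bootstrap MD is exact for degenerate contrasts", {
  a <- c(4, 5, 6, 7)
  same <- bootstrap_mean_difference(a, a, reps = 200, seed = 1)
  expect_equal(same$md, 0)
  expect_lte(same$ci_low, 0)
  expect_gte(same$ci_high, 0)
  shift <- bootstrap_mean_difference(a, a + 5, reps = 200, seed = 1)
  expect_equal(shift$md, 5)
  const <- bootstrap_mean_difference(rep(3, 10), rep(8, 10),
                                     reps = 200, seed = 1)
  expect_equal(c(const$ci_low, const$ci_high), c(5, 5))
  expect_error(bootstrap_mean_difference(numeric(0), a), "non-empty")
  expect_warning(bootstrap_mean_difference(a, a, reps = 50, seed = 1),
                 "100")
})

test_that("bootstrap is deterministic under a seed", {
  set.seed(77); a <- rnorm(40); b <- rnorm(35, 0.3)
  r1 <- bootstrap_mean_difference(a, b, seed = 5)
  r2 <- bootstrap_mean_difference(a, b, seed = 5)
  expect_identical(r1$boot, r2$boot)
})

test_that("log-scale Cohen's d uses pooled SD and the printed bins", {
  set.seed(3)
  x <- rnorm(50)
  expect_error(cohens_d_log(rep(1, 5), rep(1, 5)), "zero pooled")
  expect_equal(cohens_d_log(x, x)$d, 0)
  expect_equal(cohens_d_log(x, x)$label, "trivial")
  # means 0 and 1, pooled SD 1 -> d = 1, moderate
  a <- c(-1, 0, 1); b <- c(0, 1, 2)
  r <- cohens_d_log(a, b)
  expect_equal(r$d, 1)
  expect_equal(r$label, "moderate")
  # closed lower bound: d = 0.2 exactly is small
  r2 <- cohens_d_log(c(-5, 0, 5), c(-4, 1, 6))  # diff 1, pooled SD 5
  expect_equal(r2$d, 0.2)
  expect_equal(r2$label, "small")
})

test_that("Bonferroni adjustment is min(1, m*p) and never below raw p", {
  p <- c(0.01, 0.04, 0.5)
  adj <- bonferroni_adjust(p)
  expect_equal(adj, pmin(1, p * 3))
  expect_true(all(adj >= p))
})

test_that("design-effect sample size matches the worked study design", {
  d <- sample_size_lmm(0.40, 0.80, 0.05, 23, 0.05)
  expect_equal(d$total_n, 331)
  expect_equal(d$obs_per_subject, 14)
  # no clustering: design effect vanishes
  d0 <- sample_size_lmm(0.40, 0.80, 0.05, 23, 0)
  expect_equal(d0$total_n, ceiling(d0$n_base))
  expect_error(sample_size_lmm(0.40, 0.80, 0.05, 5, 0.05),
               "unsolvable")
})

test_that("mixed model flags factors with too few levels and degenerate effects", {
  d <- planted_frame(seed = 4)
  d1 <- d[d$season_period == "regular", ]
  expect_error(fit_lmm(d1, "y", "season_period * role"),
               "fewer than 2")
  # balanced two-level factor with identical group values -> F ~ 0
  set.seed(8)
  pairs <- expand.grid(subj = 1:10, pair = 1:3)
  vals <- rnorm(10)[pairs$subj] + rnorm(30, 0, 0.5)
  d2 <- data.frame(player_id = sprintf("p%d", rep(pairs$subj, 2)),
                   g = rep(c("a", "b"), each = 30),
                   y = rep(vals, 2))
  f <- fit_lmm(d2, "y", "g")
  expect_lt(f$anova$F[1], 1e-6)
})

test_that("decision tree takes the planted branch", {
  # strong 3-way interaction
  d3 <- planted_frame(three_way = 3, seed = 10)
  t3 <- interaction_decision_tree(d3, "y")
  expect_equal(t3$branch, "three_way_interaction")
  expect_true(is.data.frame(t3$follow_up))
  # pure period main effect
  dm <- planted_frame(period_effect = 1.5, seed = 11)
  tm <- interaction_decision_tree(dm, "y")
  expect_equal(tm$branch, "period_main_effect")
  expect_lte(lmm_p <- tm$models$reduced$anova$p[
    tm$models$reduced$anova$term == "season_period"], 0.05)
  # period x role interaction without team involvement
  dr <- planted_frame(role_period = c(starter = 2, in_rotation = 0,
                                      out_rotation = -2), seed = 15)
  tr <- interaction_decision_tree(dr, "y")
  expect_equal(tr$branch, "period_role_interaction")
  expect_setequal(tr$follow_up$role,
                  c("starter", "in_rotation", "out_rotation"))
  # branch log records every decision
  expect_true(all(c("term", "p", "verdict") %in% names(tr$log)))
})

test_that("decision tree names empty cells that preclude a branch", {
  d <- planted_frame(seed = 13)
  d <- d[!(d$role == "starter" & d$team == "men"), ]
  expect_error(interaction_decision_tree(d, "y"), "empty cell")
})

test_that("null data rarely produce spurious branch decisions", {
  branches <- vapply(1:20, function(s) {
    d <- planted_frame(seed = 100 + s)
    interaction_decision_tree(d, "y")$branch
  }, character(1))
  expect_gte(mean(branches == "period_main_effect"), 0.75)
})

test_that("report tables render median (Q1-Q3) cells", {
  expect_equal(format_median_iqr(c(1, 2, 3, 4, 5)), "3.0 (2.0–4.0)")
  expect_equal(format_median_iqr(7), "7.0 (7.0–7.0)")
  expect_true(is.na(format_median_iqr(numeric(0))))
  s <- data.frame(season_period = rep(c("regular", "finals"), each = 5),
                  role = "starter",
                  minutes_played = c(1:5, 11:15))
  tab <- report_tables(s, "minutes_played")
  cell <- tab$cell[tab$role == "starter" &
                     tab$season_period == "regular"]
  expect_equal(cell, "3.0 (2.0–4.0)")
  expect_true(is.na(tab$cell[tab$role == "in_rotation" &
                               tab$season_period == "regular"]))
})
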