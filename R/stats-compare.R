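#' Shapiro-Wilk normality screen
#'
#' Shapiro-Wilk W and p for each supplied variable, flagging those
#' rejected at the 5% level. For series longer than the test's 5000-
#' observation limit an evenly spaced deterministic subsample is used.
#'
#' @param x numeric vector, or data frame of numeric columns.
#' @return Data frame `variable, W, p, non_normal`.
#' @export
normality_check <- function(x) {
  if (is.data.frame(x)) {
    out <- lapply(names(x), function(nm) {
      r <- normality_check(x[[nm]])
      r$variable <- nm
      r
    })
    return(do.call(rbind, out)[, c("variable", "W", "p", "non_normal")])
  }
  x <- x[is.finite(x)]
  if (length(x) < 3) stop_("need at least 3 observations")
  if (length(unique(x)) == 1) stop_("constant input: test undefined")
  if (length(x) > 5000)
    x <- x[round(seq(1, length(x), length.out = 5000))]
  t <- shapiro.test(x)
  data.frame(variable = NA_character_, W = unname(t$statistic),
             p = t$p.value, non_normal = t$p.value < 0.05,
             stringsAsFactors = FALSE)
}

#' Log-transform demand variables before parametric analysis
#'
#' Applies `ln(y + 1)` to the listed offset variables (those that can
#' contain zeros: minutes played and absolute/relative maximal and
#' supramaximal activity) and `ln(y)` to every other requested
#' variable. The transform is recorded on the result so it can be
#' inverted.
#'
#' @param frame analysis frame.
#' @param variables columns to transform.
#' @param offset_variables subset of `variables` receiving the +1
#'   offset.
#' @param suffix suffix for the new columns (`""` replaces in place).
#' @return `frame` with transformed columns and a `log_transform`
#'   attribute mapping each variable to its offset.
#' @export
log_transform <- function(frame, variables,
                          offset_variables = c(
                            "minutes_played", "min_maximal",
                            "min_supramaximal", "pct_maximal",
                            "pct_supramaximal"),
                          suffix = "_log") {
  offsets <- numeric(0)
  for (v in variables) {
    y <- frame[[v]]
    if (is.null(y)) stop_("variable '", v, "' not found")
    if (any(y < 0, na.rm = TRUE))
      stop_("variable '", v, "' has negative values")
    off <- if (v %in% offset_variables) 1 else 0
    if (off == 0 && any(y == 0, na.rm = TRUE))
      stop_("variable '", v,
            "' contains zeros but is not an offset variable")
    frame[[paste0(v, suffix)]] <- log(y + off)
    offsets[v] <- off
  }
  attr(frame, "log_transform") <- offsets
  frame
}

#' Bootstrap mean difference with percentile confidence interval
#'
#' Mean difference `mean(b) - mean(a)` on the original units with a
#' percentile bootstrap CI. Resampling is within group; when subject
#' identifiers are supplied, observations are resampled within subject
#' (stratified, cluster-aware). Each stratum of size n contributes
#' n - 1 resampled observations, the standard stratified-bootstrap
#' correction that keeps the variance estimate unbiased when strata
#' are small (without it, a stratum of size n understates its variance
#' by the factor (n - 1)/n).
#'
#' @param a,b numeric samples (e.g. regular season and finals).
#' @param reps bootstrap replicates.
#' @param seed RNG seed (results deterministic given it).
#' @param subjects_a,subjects_b optional subject ids aligned with
#'   `a`/`b`.
#' @param conf confidence level.
#' @param label contrast label carried on the result.
#' @return A `courtload_comparison` list: `label`, `md`, `ci_low`,
#'   `ci_high`, `reps`, `boot` (the bootstrap distribution).
#' @export
bootstrap_mean_difference <- function(a, b, reps = 1000, seed = 1,
                                      subjects_a = NULL,
                                      subjects_b = NULL, conf = 0.95,
                                      label = "finals - regular") {
  if (!length(a) || !length(b)) stop_("both groups must be non-empty")
  if (reps < 100)
    warning("fewer than 100 bootstrap replicates; CI will be unstable")
  md <- mean(b) - mean(a)
  strata_idx <- function(subj, n)
    if (is.null(subj)) list(seq_len(n)) else split(seq_len(n), subj)
  ia <- strata_idx(subjects_a, length(a))
  ib <- strata_idx(subjects_b, length(b))
  draw <- function(strata) unlist(lapply(strata, function(ix) {
    m <- if (length(strata) > 1) max(length(ix) - 1L, 1L)
    else length(ix)
    ix[sample.int(length(ix), m, replace = TRUE)]
  }), use.names = FALSE)
  boot <- with_seed_(seed, {
    vapply(seq_len(reps), function(r)
      mean(b[draw(ib)]) - mean(a[draw(ia)]), numeric(1))
  })
  ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE, type = 7)
  structure(list(label = label, md = md, ci_low = ci[1],
                 ci_high = ci[2], conf = conf, reps = reps,
                 boot = boot),
            class = "courtload_comparison")
}

#' @export
print.courtload_comparison <- function(x, ...) {
  cat(sprintf("%s: MD = %.2f (%.0f%% CI %.2f to %.2f)\n", x$label,
              x$md, 100 * x$conf, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cohen's d on log-transformed values
#'
#' Absolute standardized mean difference with pooled SD, computed on
#' log-scale values, labeled trivial (<0.2), small (0.2--0.6), moderate
#' (>0.6--1.2), large (>1.2--2.0) or very large (>2.0). The lower bound
#' of each closed bin belongs to that bin (d = 0.2 is small).
#'
#' @param a_log,b_log log-transformed samples, each of length >= 2.
#' @return List with `d` and `label`.
#' @export
cohens_d_log <- function(a_log, b_log) {
  n1 <- length(a_log); n2 <- length(b_log)
  if (n1 < 2 || n2 < 2) stop_("each group needs at least 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(a_log) +
                (n2 - 1) * stats::var(b_log)) / (n1 + n2 - 2))
  if (sp == 0) stop_("zero pooled SD: effect size undefined")
  d <- abs(mean(b_log) - mean(a_log)) / sp
  label <- if (d < 0.2) "trivial" else if (d <= 0.6) "small"
  else if (d <= 1.2) "moderate" else if (d <= 2.0) "large"
  else "very large"
  list(d = d, label = label)
}

#' Bonferroni adjustment for a family of pairwise contrasts
#'
#' `p_adj = min(1, p * m)` for `m` contrasts; never smaller than the
#' raw p.
#'
#' @param p raw p-values of the family.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) p.adjust(p, method = "bonferroni")

#' Format a cell as median (Q1--Q3)
#'
#' Quartiles use the linear-interpolation convention (R type 7).
#'
#' @param x values in the cell.
#' @param digits decimal places.
#' @return Character scalar, `NA` for an empty cell.
#' @export
format_median_iqr <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  q <- quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  sprintf(paste0("%.", digits, "f (%.", digits, "f–%.", digits,
                 "f)"), q[1], q[2], q[3])
}

#' Demand tables by role and season period
#'
#' Median (Q1--Q3) of each requested variable per role-by-period cell
#' plus an all-roles column, in the layout of a session-demands table.
#' Values are summarized on original units; empty cells render as
#' missing.
#'
#' @param summaries session-summary frame.
#' @param variables columns to tabulate.
#' @param digits decimal places per cell.
#' @return Long data frame `variable, role, season_period, cell`.
#' @export
report_tables <- function(summaries, variables, digits = 1) {
  roles <- c(ROLE_LEVELS, "all")
  periods <- unique(as.character(summaries$season_period))
  grid <- expand.grid(variable = variables, role = roles,
                      season_period = periods,
                      stringsAsFactors = FALSE)
  grid$cell <- vapply(seq_len(nrow(grid)), function(i) {
    rows <- summaries$season_period == grid$season_period[i] &
      (grid$role[i] == "all" | summaries$role == grid$role[i])
    format_median_iqr(summaries[rows, grid$variable[i]], digits)
  }, character(1))
  grid
}
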