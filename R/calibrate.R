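#' Estimated oxygen uptake for a running speed
#'
#' Maps a shuttle-stage speed to estimated oxygen uptake. The default
#' mapping is the ACSM metabolic equation for running,
#' VO2 = 0.2 x speed (m·min^-1) + 3.5 ml·kg^-1·min^-1; an alternative
#' mapping can be injected wherever this is used.
#'
#' @param speed_kmh speed, km/h (vectorized).
#' @return Estimated VO2, ml·kg^-1·min^-1.
#' @examples
#' estimate_vo2_for_speed(12)  # 200 m/min -> 43.5
#' @export
estimate_vo2_for_speed <- function(speed_kmh) {
  if (any(speed_kmh < 0)) stop_("speed must be non-negative")
  0.2 * (speed_kmh * 1000 / 60) + 3.5
}

#' Fit a per-player linear AvF_NET to VO2 calibration
#'
#' Ordinary least squares of estimated VO2 on stage AvF_NET across the
#' completed Yo-Yo IR1 stages, giving the individualized linear
#' relationship used to express %VO2-reserve intensity bands as force
#' thresholds.
#'
#' @param avf_net stage AvF_NET values, newtons.
#' @param vo2 stage estimated VO2, ml·kg^-1·min^-1.
#' @param vo2_rest resting VO2, ml·kg^-1·min^-1.
#' @param vo2_max maximal VO2; defaults to the VO2 of the last (highest)
#'   stage supplied.
#' @param player_id identifier.
#' @return A `calibration_model` list: `slope` (ml·kg^-1·min^-1 per N),
#'   `intercept`, `r_squared`, `vo2_rest`, `vo2_max`, `player_id`.
#' @export
fit_calibration <- function(avf_net, vo2, vo2_rest = 3.5, vo2_max = NULL,
                            player_id = NA_character_) {
  if (length(avf_net) < 2 || length(vo2) != length(avf_net))
    stop_("need at least two (AvF_NET, VO2) stage pairs")
  if (length(unique(avf_net)) < 2)
    stop_("calibration unidentifiable: all AvF_NET values equal")
  fit <- lm(vo2 ~ avf_net)
  slope <- unname(coef(fit)[2])
  if (is.na(slope)) stop_("calibration fit failed")
  if (slope <= 0)
    warning("calibration slope is not positive; check stage data")
  if (is.null(vo2_max)) vo2_max <- vo2[which.max(avf_net)]
  if (vo2_max <= vo2_rest) stop_("vo2_max must exceed vo2_rest")
  sst <- sum((vo2 - mean(vo2))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(player_id = player_id, slope = slope,
                 intercept = unname(coef(fit)[1]), r_squared = r2,
                 vo2_rest = vo2_rest, vo2_max = vo2_max),
            class = "calibration_model")
}

#' Percentage of oxygen-uptake reserve
#'
#' %VO2R = 100 (VO2 - VO2rest) / (VO2max - VO2rest). Values above 100
#' indicate supramaximal work.
#'
#' @param vo2 oxygen uptake, ml·kg^-1·min^-1 (vectorized).
#' @param vo2_rest,vo2_max resting and maximal VO2.
#' @return %VO2R.
#' @export
vo2r_percent <- function(vo2, vo2_rest, vo2_max) {
  if (vo2_max <= vo2_rest) stop_("vo2_max must exceed vo2_rest")
  100 * (vo2 - vo2_rest) / (vo2_max - vo2_rest)
}

#' Personalized intensity-band force thresholds
#'
#' Converts the five %VO2R intensity bands — inactive (<=10%), light
#' (>10--40%), moderate-vigorous (>40--90%), maximal (>90--100%) and
#' supramaximal (>100%) — into AvF_NET thresholds for one player by
#' mapping each band edge to VO2 and inverting the player's linear
#' calibration: F_edge = (VO2_edge - intercept) / slope. Negative
#' inverted forces are clamped to zero.
#'
#' @param model a `calibration_model` from [fit_calibration()].
#' @param edges_pct band edges in %VO2R.
#' @return An `intensity_bands` list with `thresholds_n` (4 strictly
#'   increasing newton values), `edges_pct`, `labels`, `player_id`.
#' @export
bands_for_player <- function(model, edges_pct = c(10, 40, 90, 100)) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0) stop_("cannot invert a non-positive slope")
  vo2_edges <- model$vo2_rest +
    edges_pct / 100 * (model$vo2_max - model$vo2_rest)
  thr <- pmax((vo2_edges - model$intercept) / model$slope, 0)
  if (any(diff(thr) <= 0))
    stop_("inverted thresholds are not strictly increasing")
  structure(list(player_id = model$player_id, edges_pct = edges_pct,
                 thresholds_n = thr, labels = BAND_LEVELS),
            class = "intensity_bands")
}

#' Classify force epochs into intensity bands
#'
#' Assigns each epoch of a force series to exactly one of the five
#' bands. Boundary semantics follow the band definitions: a value
#' exactly at a threshold belongs to the lower band (inactive is
#' `<=` its threshold, higher bands open below, closed above).
#'
#' @param force a `force_series` (or numeric vector of epoch forces, N).
#' @param bands an `intensity_bands` object.
#' @return Factor of band labels, one per epoch, levels in intensity
#'   order.
#' @export
classify_epochs <- function(force, bands) {
  stopifnot(inherits(bands, "intensity_bands"))
  x <- as.numeric(unclass(force))
  cut(x, breaks = c(-Inf, bands$thresholds_n, Inf), labels = bands$labels,
      right = TRUE)
}

#' Representative mid-band forces
#'
#' Newton value at the centre of each closed band and 110% of the top
#' threshold for the open supramaximal band. Used by the synthetic
#' generator to plant epoch intensities, and handy for plotting.
#'
#' @param bands an `intensity_bands` object.
#' @return Named numeric vector, one force per band.
#' @export
band_centers <- function(bands) {
  t <- bands$thresholds_n
  setNames(c(t[1] / 2, (t[1] + t[2]) / 2, (t[2] + t[3]) / 2,
             (t[3] + t[4]) / 2, 1.1 * t[4]), bands$labels)
}
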