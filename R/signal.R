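#' Construct a triaxial acceleration trace
#'
#' Container for one player-session of uniformly sampled triaxial
#' acceleration in g. Stored as a data frame with columns
#' `timestamp_s, ax_g, ay_g, az_g` plus sample-rate and identity
#' attributes.
#'
#' @param ax,ay,az numeric vectors of equal length, acceleration in g.
#' @param sample_rate sampling rate, Hz.
#' @param player_id,session_id identifiers carried through the pipeline.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(ax, ay, az, sample_rate, player_id = NA_character_,
                        session_id = NA_character_) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop_("axes must have equal length")
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop_("trace contains non-finite samples")
  if (sample_rate <= 0) stop_("sample_rate must be positive")
  structure(
    data.frame(timestamp_s = (seq_len(n) - 1) / sample_rate,
               ax_g = ax, ay_g = ay, az_g = az),
    sample_rate = sample_rate, player_id = player_id,
    session_id = session_id,
    class = c("accel_trace", "data.frame"))
}

trace_rate_ <- function(trace) {
  r <- attr(trace, "sample_rate")
  if (is.null(r)) stop_("trace has no sample_rate attribute")
  r
}

#' Zero-phase Butterworth band-pass filter for acceleration traces
#'
#' Applies a Butterworth band-pass (default 0.1--15 Hz, overall order 4,
#' i.e. two poles per band edge) to each axis. Filtering is zero-phase
#' (forward-backward), so event timing is preserved for epoch banding;
#' the effective magnitude response is therefore the squared single-pass
#' response. The DC component (gravity) lies below the low cut-off and is
#' removed.
#'
#' @param trace an [accel_trace()].
#' @param low,high band edges, Hz; must satisfy `0 < low < high <`
#'   Nyquist.
#' @param order overall band-pass order (even; `order/2` poles per edge).
#' @return A filtered `accel_trace` (timestamps unchanged).
#' @examples
#' tr <- accel_trace(rep(0.3, 400), rep(0, 400), rep(1, 400), 100)
#' f <- bandpass_filter(tr)
#' max(abs(colMeans(f[, 2:4])))  # constant axes are removed
#' @export
bandpass_filter <- function(trace, low = 0.1, high = 15, order = 4) {
  fs <- trace_rate_(trace)
  if (!(low > 0 && high > low && high < fs / 2))
    stop_("cut-offs must satisfy 0 < low < high < Nyquist (", fs / 2,
          " Hz)")
  if (order < 2 || order %% 2 != 0)
    stop_("order must be a positive even integer")
  if (nrow(trace) <= 3 * order)
    stop_("trace too short to filter (need > ", 3 * order, " samples)")
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  out <- trace
  for (col in c("ax_g", "ay_g", "az_g")) {
    # remove the DC component (gravity) before filtering: the pass-band
    # excludes it anyway, and a large constant offset otherwise excites
    # end transients in the zero-initialized forward-backward pass
    x <- trace[[col]]
    out[[col]] <- signal::filtfilt(bf, x - mean(x))
  }
  out
}

#' Closed-form Butterworth band-pass magnitude response
#'
#' Analytic magnitude of the digital Butterworth band-pass produced by
#' bilinear transformation of the order-`order/2` low-pass prototype
#' (band edges pre-warped), i.e. the transfer magnitude of the filter
#' [bandpass_filter()] applies in a single pass. Used as an independent
#' oracle for the implemented filter's frequency response.
#'
#' @param f frequencies at which to evaluate, Hz.
#' @param low,high,order as in [bandpass_filter()].
#' @param fs sampling rate, Hz.
#' @return Magnitude response (single pass) at `f`.
#' @export
butterworth_bandpass_response <- function(f, low = 0.1, high = 15,
                                          order = 4, fs = 100) {
  # bilinear pre-warping: digital frequency x maps to analog tan(pi*x/fs)
  wl <- tan(pi * low / fs)
  wh <- tan(pi * high / fs)
  w <- tan(pi * f / fs)
  n <- order / 2
  ratio <- (w^2 - wl * wh) / (w * (wh - wl))
  1 / sqrt(1 + ratio^(2 * n))
}

#' Resultant acceleration magnitude
#'
#' Per-sample Euclidean magnitude sqrt(ax^2 + ay^2 + az^2) of a
#' (typically filtered) trace, in g.
#'
#' @param trace an [accel_trace()].
#' @return Numeric vector of magnitudes, one per sample.
#' @export
resultant_acceleration <- function(trace) {
  sqrt(trace$ax_g^2 + trace$ay_g^2 + trace$az_g^2)
}

#' Epoch-level net force series
#'
#' Converts a resultant-acceleration magnitude series (g) to net force in
#' newtons (magnitude x 9.81 m s^-2 x body mass) and averages it within
#' consecutive epochs. The trailing partial epoch, if any, is dropped
#' (series length differs from trace duration by at most one epoch).
#'
#' @param magnitude per-sample resultant magnitudes, g.
#' @param body_mass player body mass, kg.
#' @param sample_rate sampling rate of `magnitude`, Hz.
#' @param epoch_length epoch, seconds.
#' @param player_id,session_id identifiers.
#' @return A `force_series` object: numeric vector of per-epoch AvF_NET
#'   values (N) with `epoch_length` attribute.
#' @export
compute_force_series <- function(magnitude, body_mass, sample_rate,
                                 epoch_length = 1,
                                 player_id = NA_character_,
                                 session_id = NA_character_) {
  if (body_mass <= 0) stop_("body mass must be positive")
  if (!length(magnitude)) stop_("empty magnitude series")
  per_epoch <- round(sample_rate * epoch_length)
  n_epochs <- length(magnitude) %/% per_epoch
  if (n_epochs < 1) stop_("series shorter than one epoch")
  m <- matrix(magnitude[seq_len(n_epochs * per_epoch)], nrow = per_epoch)
  force <- colMeans(m) * 9.81 * body_mass
  structure(force, epoch_length = epoch_length, player_id = player_id,
            session_id = session_id, class = "force_series")
}

#' Session intensity (AvF_NET) and volume (impulse)
#'
#' `session_intensity()` is the mean of the per-epoch force series,
#' in newtons — the session's AvF_NET. `session_impulse()` is intensity
#' multiplied by duration, reported in kN·s.
#'
#' @param force a `force_series` from [compute_force_series()].
#' @param duration_s session duration in seconds; defaults to the extent
#'   of the force series.
#' @return Scalar intensity (N) or impulse (kN·s).
#' @examples
#' fs <- structure(rep(215, 60), epoch_length = 1, class = "force_series")
#' session_impulse(fs, duration_s = 5665)  # 215 N over 5665 s -> kN·s
#' @export
session_intensity <- function(force) {
  if (!length(force)) stop_("empty force series")
  mean(unclass(force))
}

#' @rdname session_intensity
#' @export
session_impulse <- function(force, duration_s = NULL) {
  if (!length(force)) stop_("empty force series")
  if (is.null(duration_s))
    duration_s <- length(force) * attr(force, "epoch_length")
  session_intensity(force) * duration_s / 1000
}

#' Full trace-to-force pipeline for one session
#'
#' Convenience chain: band-pass filter, resultant, epoch force series.
#'
#' @param trace an [accel_trace()].
#' @param body_mass kg.
#' @param low,high,order filter settings (see [bandpass_filter()]).
#' @param epoch_length seconds.
#' @return A `force_series`.
#' @export
trace_to_force <- function(trace, body_mass, low = 0.1, high = 15,
                           order = 4, epoch_length = 1) {
  filt <- bandpass_filter(trace, low = low, high = high, order = order)
  mag <- resultant_acceleration(filt)
  compute_force_series(mag, body_mass, trace_rate_(trace), epoch_length,
                       player_id = attr(trace, "player_id"),
                       session_id = attr(trace, "session_id"))
}
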