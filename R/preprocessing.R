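#' Low-pass filter specification
#'
#' Defaults follow the standard postural-sway preprocessing choice: a
#' 4th-order Butterworth low-pass at 7 Hz, applied forward-backward
#' (zero-phase) so that filtering does not shift the COP signal in time.
#'
#' @param order Filter order (per pass).
#' @param cutoff_hz Cut-off frequency in Hz; must lie below the Nyquist
#'   frequency of the series it is applied to.
#' @param zero_phase If `TRUE` (default), the filter is applied forward
#'   and backward, giving zero phase distortion and a squared magnitude
#'   response; if `FALSE`, a single causal pass is used.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 7, zero_phase = TRUE) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) {
    stop("cutoff_hz must be positive", call. = FALSE)
  }
  structure(list(order = order, cutoff_hz = as.numeric(cutoff_hz),
                 kind = "low", zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Steady-state initial filter state for a step input of unit amplitude
# (direct-form II transposed). Starting the recursion from zi * x[1]
# makes a constant input map to an exactly constant output, removing the
# startup transient.
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1L) return(numeric(0))
  # companion matrix of a
  comp <- rbind(-a[-1], cbind(diag(1, n - 2L), rep(0, n - 2L)))
  IminusA <- diag(1, n - 1L) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

.apply_pass <- function(b, a, x, zi) {
  iir_filter_cpp(b, a, x, zi * x[1])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a series with a Butterworth low-pass of the given order and
#' cut-off. Edge effects are handled by odd-symmetric (point-reflected)
#' padding of length `3 * (order + 1)` at both ends, and each pass starts
#' from the filter's steady state for the first padded sample, so a
#' constant series passes through unchanged (unit DC gain) to machine
#' precision. With `zero_phase = TRUE` the padded series is filtered
#' forward, reversed, filtered again and reversed, which cancels the
#' phase response and squares the magnitude response.
#'
#' @param x Numeric series.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate of `x` in Hz.
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (spec$cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %g Hz is at or above the Nyquist frequency %g Hz",
                 spec$cutoff_hz, fs / 2), call. = FALSE)
  }
  n <- length(x)
  if (n <= 3L * spec$order) {
    stop(sprintf("series length %d too short for order-%d filtering (need > %d)",
                 n, spec$order, 3L * spec$order), call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  len <- max(length(bt$b), length(bt$a))
  b <- c(bt$b, rep(0, len - length(bt$b)))
  a <- c(bt$a, rep(0, len - length(bt$a)))
  zi <- .lfilter_zi(b, a)

  pad <- min(3L * (spec$order + 1L), n - 1L)
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(pre, x, post)

  y <- .apply_pass(b, a, xp, zi)
  if (spec$zero_phase) {
    y <- rev(.apply_pass(b, a, rev(y), zi))
  }
  y[(pad + 1L):(pad + n)]
}

#' First-difference (increment) series
#'
#' Returns the COP displacement increment series `out[i] = x[i+1] - x[i]`,
#' the series on which sample entropy is evaluated. The output has length
#' `length(x) - 1` and telescopes: `sum(increments(x)) == x[n] - x[1]`.
#'
#' @param x Numeric series of length >= 2.
#' @param direction Optional label (`"AP"` or `"ML"`) attached as an
#'   attribute.
#' @return Numeric vector of increments.
#' @export
increments <- function(x, direction = NULL) {
  if (length(x) < 2L) stop("need at least 2 samples to difference",
                           call. = FALSE)
  out <- diff(x)
  if (!is.null(direction)) {
    attr(out, "direction") <- match.arg(direction, c("AP", "ML"))
  }
  out
}

#' Preprocess one trial: filter, COP, increments
#'
#' Applies the full single-trial preprocessing chain in the stated order:
#' low-pass filter the six raw channels, compute the COP trajectory, then
#' take the first-difference of each COP direction. For a 30 s trial at
#' 50 Hz (1500 samples) each increment series has 1499 samples. Setting
#' `filter_target = "cop"` instead filters the COP signal computed from
#' raw channels, for sensitivity analysis.
#'
#' @param rec A [force_plate_recording()].
#' @param spec A [filter_spec()].
#' @param filter_target `"channels"` (default) or `"cop"`.
#' @param fz_min,axis_rotation_deg Passed to [compute_cop()].
#' @return A list with elements `ap` and `ml` (increment series), plus
#'   `cop` (the filtered-stage `cop_trajectory`) and `meta`.
#' @export
preprocess_trial <- function(rec, spec = filter_spec(),
                             filter_target = c("channels", "cop"),
                             fz_min = 10, axis_rotation_deg = 0) {
  stopifnot(inherits(rec, "force_plate_recording"))
  filter_target <- match.arg(filter_target)
  if (filter_target == "channels") {
    ch <- rec$channels
    for (nm in names(ch)) {
      ch[[nm]] <- butterworth_lowpass(ch[[nm]], spec, rec$fs)
    }
    frec <- force_plate_recording(ch$fx, ch$fy, ch$fz, ch$mx, ch$my, ch$mz,
                                  fs = rec$fs, meta = rec$meta)
    cop <- compute_cop(frec, fz_min = fz_min,
                       axis_rotation_deg = axis_rotation_deg)
  } else {
    cop <- compute_cop(rec, fz_min = fz_min,
                       axis_rotation_deg = axis_rotation_deg)
    cop$ap <- butterworth_lowpass(cop$ap, spec, rec$fs)
    cop$ml <- butterworth_lowpass(cop$ml, spec, rec$fs)
  }
  list(ap = increments(cop$ap, "AP"),
       ml = increments(cop$ml, "ML"),
       cop = cop, meta = rec$meta)
}
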