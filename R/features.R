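# Causal feature extraction: low-pass filtered component (LFC) and
# normalized band-amplitude envelopes.

#' Causal Savitzky-Golay FIR coefficients
#'
#' Least-squares polynomial fit of the given order to a trailing window of
#' `m` samples, evaluated at the newest window point. Returns the FIR weights
#' ordered oldest to newest.
#'
#' @param order polynomial order.
#' @param m window length in samples, must be >= order + 1.
#' @return numeric vector of length `m`.
#' @export
savgol_causal_coeffs <- function(order, m) {
  if (m < order + 1L) stop("window must contain at least order + 1 samples")
  V <- outer((-(m - 1L)):0, 0:order, "^")
  drop(V[m, ] %*% solve(crossprod(V), t(V)))
}

#' Causal Savitzky-Golay smoothing
#'
#' Smooths a signal with a causal variant of the Savitzky-Golay filter: at
#' each time the output is the value, at the newest point, of the
#' least-squares polynomial fitted to the trailing window ending there. No
#' future samples are used. During the first window (`warm-up`) the window
#' grows from `order + 1` samples; the warm-up length is attached as
#' attribute `"warmup"` (number of samples before the first full window).
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param order polynomial order (default 2).
#' @param window_s window length in seconds (default 0.25).
#' @return numeric vector like `x` with attribute `warmup`.
#' @export
savgol_causal <- function(x, rate, order = 2L, window_s = 0.25) {
  m <- round(rate * window_s)
  if (m < order + 1L)
    stop("window of ", m, " samples is shorter than order + 1 = ", order + 1L)
  h <- savgol_causal_coeffs(order, m)
  y <- as.numeric(stats::filter(x, rev(h), sides = 1L))
  # growing-window fits over the warm-up span
  for (i in seq_len(min(m - 1L, length(x)))) {
    if (i <= order + 1L) {
      y[i] <- x[i]   # <= order+1 points: LS fit interpolates the newest point
    } else {
      y[i] <- sum(savgol_causal_coeffs(order, i) * x[seq_len(i)])
    }
  }
  attr(y, "warmup") <- m - 1L
  y
}

#' Elliptic band filter design
#'
#' Causal elliptic digital filter of design order 4 for one analysis band:
#' a band-pass between `f_lo` and `f_hi`, degenerating to a low-pass at
#' `f_hi` when `f_lo = 0` (a band-pass cannot have a zero-frequency edge).
#' Passband ripple 0.5 dB, stopband attenuation 50 dB.
#'
#' @param rate sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= rate/2`. A band
#'   starting at 0 degenerates to a low-pass at `f_hi`; a band ending
#'   exactly at Nyquist degenerates to a high-pass at `f_lo`.
#' @param n design order (default 4).
#' @param rp passband ripple in dB.
#' @param rs stopband attenuation in dB.
#' @return a `signal::Arma` filter object.
#' @export
ellip_band <- function(rate, f_lo, f_hi, n = 4L, rp = 0.5, rs = 50) {
  if (f_lo < 0 || f_lo >= f_hi) stop("need 0 <= f_lo < f_hi")
  if (f_hi > rate / 2) stop("band edge ", f_hi, " Hz above Nyquist (",
                            rate / 2, " Hz)")
  if (f_lo == 0 && f_hi == rate / 2)
    stop("band covers the whole spectrum: nothing to filter")
  if (f_lo == 0)
    signal::ellip(n, rp, rs, f_hi / (rate / 2), type = "low")
  else if (f_hi == rate / 2)
    signal::ellip(n, rp, rs, f_lo / (rate / 2), type = "high")
  else
    signal::ellip(n, rp, rs, c(f_lo, f_hi) / (rate / 2), type = "pass")
}

# band-pass transient allowance (seconds) flagged as warm-up on envelopes
BP_WARMUP_S <- 1

#' Band-amplitude envelope
#'
#' Causal amplitude envelope of one frequency band: elliptic band-pass
#' filtering, rectification (absolute value), and smoothing with the causal
#' Savitzky-Golay low-pass. The envelope is clamped at zero (the polynomial
#' smoother can overshoot slightly below zero). Warm-up covers the band-pass
#' transient plus the smoother window.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz.
#' @param ... passed to [ellip_band()].
#' @return non-negative numeric vector with attribute `warmup`.
#' @export
band_amplitude <- function(x, rate, f_lo, f_hi, ...) {
  flt <- ellip_band(rate, f_lo, f_hi, ...)
  bp <- as.numeric(signal::filter(flt, x))
  env <- savgol_causal(abs(bp), rate)
  w <- attr(env, "warmup")
  env <- pmax(as.numeric(env), 0)
  attr(env, "warmup") <- w + round(BP_WARMUP_S * rate)
  env
}

#' One extracted signal component
#'
#' @param values channels x time numeric matrix.
#' @param rate sampling rate of `values` in Hz.
#' @param kind `"LFC"` or `"band-amplitude"`.
#' @param band `c(f_lo, f_hi)` in Hz for band-amplitude components.
#' @param warmup number of leading samples with undefined filter state.
#' @param t0 time of the first sample (seconds).
#' @return an object of class `SignalComponent`.
#' @export
signal_component <- function(values, rate, kind, band = NULL, warmup = 0L,
                             t0 = 0) {
  kind <- match.arg(kind, c("LFC", "band-amplitude"))
  if (kind == "band-amplitude" && is.null(band))
    stop("band-amplitude components need `band`")
  structure(list(values = values, rate = rate, kind = kind, band = band,
                 warmup = as.integer(warmup), t0 = t0),
            class = "SignalComponent")
}

#' @export
print.SignalComponent <- function(x, ...) {
  lab <- if (x$kind == "LFC") "LFC" else
    sprintf("band-amplitude %g-%g Hz", x$band[1], x$band[2])
  cat(sprintf("SignalComponent [%s]: %d channel(s), %d samples @ %g Hz\n",
              lab, nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

#' Low-pass filtered component of a recording
#'
#' @param rec a [recording()].
#' @param order,window_s Savitzky-Golay parameters (defaults 2, 0.25 s).
#' @return a `SignalComponent` of kind `"LFC"` at the native rate.
#' @export
lfc <- function(rec, order = 2L, window_s = 0.25) {
  out <- rec$samples
  w <- 0L
  for (i in seq_len(nrow(out))) {
    y <- savgol_causal(rec$samples[i, ], rec$rate, order, window_s)
    w <- attr(y, "warmup")
    out[i, ] <- y
  }
  signal_component(out, rec$rate, "LFC", warmup = w, t0 = rec$t0)
}

#' Normalized 4 Hz band-amplitude stack
#'
#' Envelopes of the 32 consecutive 4 Hz bands from 0 to 128 Hz, each
#' normalized by its average amplitude over the whole recording time so that
#' every band/channel time-average is 1. Requires a sampling rate of at
#' least 256 Hz (Nyquist for the 128 Hz upper edge).
#'
#' @param rec a [recording()].
#' @return an object of class `BandStack`: `values` (channels x 32 x time),
#'   `band_edges` (0, 4, ..., 128), `rate`, `warmup`, `t0`.
#' @export
band_stack <- function(rec) {
  if (rec$rate < 256)
    stop("rate ", rec$rate, " Hz < 256 Hz: insufficient Nyquist margin for the 128 Hz edge")
  edges <- seq(0, 128, by = 4)
  nch <- n_channels(rec)
  vals <- array(0, dim = c(nch, 32L, n_samples(rec)))
  w <- 0L
  for (b in seq_len(32L)) {
    for (i in seq_len(nch)) {
      env <- band_amplitude(rec$samples[i, ], rec$rate, edges[b], edges[b + 1L])
      w <- attr(env, "warmup")
      m <- mean(env)
      if (m <= 0) stop(sprintf("channel %s has zero amplitude in band %g-%g Hz",
                               rec$channel_ids[i], edges[b], edges[b + 1L]))
      vals[i, b, ] <- env / m
    }
  }
  structure(list(values = vals, band_edges = edges, rate = rec$rate,
                 warmup = as.integer(w), t0 = rec$t0,
                 channel_ids = rec$channel_ids),
            class = "BandStack")
}

#' Average normalized bands into one component
#'
#' Unweighted mean over the constituent normalized 4 Hz bands between `f_lo`
#' and `f_hi` (both multiples of 4 in \[0, 128\]).
#'
#' @param stack a [band_stack()].
#' @param f_lo,f_hi band edges in Hz.
#' @return a `SignalComponent` of kind `"band-amplitude"`.
#' @export
average_bands <- function(stack, f_lo, f_hi) {
  stopifnot(inherits(stack, "BandStack"))
  if (f_lo %% 4 != 0 || f_hi %% 4 != 0 || f_lo < 0 || f_hi > 128 || f_lo >= f_hi)
    stop("band edges must be multiples of 4 Hz with 0 <= f_lo < f_hi <= 128")
  idx <- (f_lo / 4 + 1L):(f_hi / 4)
  vals <- stack$values[, idx, , drop = FALSE]
  out <- apply(vals, c(1L, 3L), mean)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  signal_component(out, stack$rate, "band-amplitude", band = c(f_lo, f_hi),
                   warmup = stack$warmup, t0 = stack$t0)
}

# ---- component extraction on the 64 Hz evaluation grid ----------------------

#' Component specifications for feature extraction
#'
#' `comp_lfc()` requests the low-pass filtered component; `comp_band(lo, hi)`
#' requests the average of normalized 4 Hz band amplitudes between `lo` and
#' `hi` Hz.
#'
#' @param f_lo,f_hi band edges in Hz, multiples of 4 in \[0, 128\].
#' @return a component specification used by [extract_components()].
#' @export
comp_lfc <- function() structure(list(kind = "LFC"), class = "comp_spec")

#' @rdname comp_lfc
#' @export
comp_band <- function(f_lo, f_hi) {
  if (f_lo %% 4 != 0 || f_hi %% 4 != 0 || f_lo < 0 || f_hi > 128 || f_lo >= f_hi)
    stop("band edges must be multiples of 4 Hz with 0 <= f_lo < f_hi <= 128")
  structure(list(kind = "band-amplitude", band = c(f_lo, f_hi)),
            class = "comp_spec")
}

decimate_causal <- function(x, dec) x[seq(1L, length(x), by = dec)]

#' Extract signal components on the evaluation grid
#'
#' Filters each requested component at the recording's native rate and
#' causally decimates to the evaluation grid (the most recent filtered value
#' at each grid time; grids are aligned to session start). Per-band
#' normalization constants are the time-averages of the decimated envelopes,
#' so each normalized band averages 1 on the evaluation grid.
#'
#' @param rec a [recording()], already re-referenced and normalized.
#' @param components list of [comp_lfc()] / [comp_band()] specifications.
#' @param eval_rate evaluation rate in Hz (default 64); must divide the
#'   recording rate.
#' @return an object of class `ComponentSet`: per-component channels x
#'   n_eval matrices, plus `eval_rate`, `t0`, `valid_from` (1-based first
#'   evaluation index past every component's warm-up), `n_eval`.
#' @export
extract_components <- function(rec, components, eval_rate = 64) {
  stopifnot(inherits(rec, "Recording"))
  dec <- rec$rate / eval_rate
  if (dec != round(dec) || dec < 1)
    stop("recording rate must be an integer multiple of eval_rate")
  dec <- as.integer(dec)
  nch <- n_channels(rec)
  n_eval <- length(decimate_causal(numeric(n_samples(rec)), dec))
  has_band <- any(vapply(components, function(cs) cs$kind == "band-amplitude",
                         TRUE))
  if (has_band && rec$rate < 256)
    stop("band components need a sampling rate of at least 256 Hz")
  # cache decimated, normalized 4 Hz envelopes keyed by lower edge
  band_cache <- new.env(parent = emptyenv())
  norm_band <- function(ch, f_lo) {
    key <- sprintf("%d_%g", ch, f_lo)
    if (!is.null(band_cache[[key]])) return(band_cache[[key]])
    env <- band_amplitude(rec$samples[ch, ], rec$rate, f_lo, f_lo + 4)
    e <- decimate_causal(as.numeric(env), dec)
    m <- mean(e)
    if (m <= 0) stop("zero band amplitude in ", f_lo, "-", f_lo + 4, " Hz")
    out <- e / m
    attr(out, "warmup_eval") <- ceiling(attr(env, "warmup") / dec)
    band_cache[[key]] <- out
    out
  }
  vals <- vector("list", length(components))
  warm <- 0L
  for (ci in seq_along(components)) {
    cs <- components[[ci]]
    mat <- matrix(0, nch, n_eval)
    if (cs$kind == "LFC") {
      for (ch in seq_len(nch)) {
        y <- savgol_causal(rec$samples[ch, ], rec$rate)
        warm <- max(warm, ceiling(attr(y, "warmup") / dec))
        mat[ch, ] <- decimate_causal(as.numeric(y), dec)
      }
    } else {
      sub <- seq(cs$band[1], cs$band[2] - 4, by = 4)
      for (ch in seq_len(nch)) {
        acc <- numeric(n_eval)
        for (f_lo in sub) {
          e <- norm_band(ch, f_lo)
          warm <- max(warm, attr(e, "warmup_eval"))
          acc <- acc + e
        }
        mat[ch, ] <- acc / length(sub)
      }
    }
    vals[[ci]] <- mat
  }
  structure(list(values = vals, components = components, eval_rate = eval_rate,
                 t0 = rec$t0, valid_from = warm + 1L, n_eval = n_eval,
                 n_channels = nch, channel_ids = rec$channel_ids),
            class = "ComponentSet")
}

#' @export
print.ComponentSet <- function(x, ...) {
  labs <- vapply(x$components, function(cs)
    if (cs$kind == "LFC") "LFC" else sprintf("%g-%g Hz", cs$band[1], cs$band[2]),
    "")
  cat(sprintf("ComponentSet: %s; %d channel(s), %d evaluations @ %g Hz\n",
              paste(labs, collapse = " + "), x$n_channels, x$n_eval,
              x$eval_rate))
  invisible(x)
}
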