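# Synthetic continuous sessions with ground-truth events and the
# event-locked structure the detection method assumes: 1/f background,
# an additive slow biphasic potential, a beta-band (16-28 Hz) amplitude
# decrease and a high-gamma (56-128 Hz) amplitude increase around events.

#' Synthetic-session configuration
#'
#' Defaults emulate a continuous grasping session: events from a gamma
#' renewal process with mean inter-event interval 5 s and a hard floor of
#' 2 s; around each event a slow biphasic potential deflection, a fractional
#' beta amplitude decrease and a fractional high-gamma amplitude increase,
#' each locked to the event up to a labeling jitter of 60 ms; per-channel
#' 1/f background noise.
#'
#' @param n_channels number of channels (default 5).
#' @param rate sampling rate in Hz (default 256).
#' @param duration_s session length in seconds (default 600).
#' @param inter_event renewal-interval model: list with `mean` (s), `floor`
#'   (minimum interval, s) and gamma `shape` for the part above the floor.
#' @param lfc_effect slow-potential transient: list with `amp` (peak size in
#'   units of the background sd), `width_s` (overall span) and `latency_s`.
#'   Shape is a biphasic difference of Gaussians.
#' @param beta_effect fractional 16-28 Hz amplitude change at events
#'   (default -0.4, a decrease).
#' @param gamma_effect fractional 56-128 Hz amplitude change at events
#'   (default 1.0, a doubling).
#' @param mod_width_s width of the raised-cosine amplitude-modulation window
#'   (default 1 s, i.e. modulation spanning about half a second on either
#'   side of the event, as in movement-related band-power changes).
#' @param jitter_s sd of the event-locking jitter (default 0.06 s).
#' @param noise list with 1/f `exponent` (power ~ 1/f^exponent) and `level`
#'   (background sd).
#' @return an object of class `SynthConfig`.
#' @export
synth_config <- function(n_channels = 5L, rate = 256, duration_s = 600,
                         inter_event = list(mean = 5, floor = 2, shape = 4),
                         lfc_effect = list(amp = 1.5, width_s = 0.6,
                                           latency_s = 0),
                         beta_effect = -0.4, gamma_effect = 1.0,
                         mod_width_s = 1, jitter_s = 0.06,
                         noise = list(exponent = 1, level = 1)) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (inter_event$mean <= inter_event$floor)
    stop("infeasible renewal model: mean interval must exceed the floor")
  structure(list(n_channels = as.integer(n_channels), rate = rate,
                 duration_s = duration_s, inter_event = inter_event,
                 lfc_effect = lfc_effect, beta_effect = beta_effect,
                 gamma_effect = gamma_effect, mod_width_s = mod_width_s,
                 jitter_s = jitter_s, noise = noise),
            class = "SynthConfig")
}

# independent reproducible sub-streams derived from one seed
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 65537) %% 2147483647)
}

#' Generate ground-truth event times
#'
#' Renewal process with shifted-gamma intervals: `floor` plus a gamma draw
#' with the configured shape, scaled so the mean interval matches
#' `inter_event$mean`. Events run from the first interval after session
#' start to one mean interval before session end.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; the same seed reproduces the same events.
#' @return an [event_list()].
#' @export
generate_events <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SynthConfig"))
  ie <- cfg$inter_event
  scale <- (ie$mean - ie$floor) / ie$shape
  set.seed(sub_seed(seed, 1L))
  t_max <- cfg$duration_s - ie$mean
  n_guess <- ceiling(cfg$duration_s / ie$mean * 2 + 10)
  iv <- ie$floor + stats::rgamma(n_guess, shape = ie$shape, scale = scale)
  tt <- cumsum(iv)
  while (tt[length(tt)] < t_max) {
    iv <- ie$floor + stats::rgamma(n_guess, shape = ie$shape, scale = scale)
    tt <- c(tt, tt[length(tt)] + cumsum(iv))
  }
  event_list(tt[tt <= t_max])
}

# 1/f^(exponent) noise via spectral shaping, unit sd
pink_noise <- function(n, rate, exponent) {
  nf <- 2^ceiling(log2(n))
  f <- seq(0, rate / 2, length.out = nf / 2 + 1)
  amp <- c(0, f[-1]^(-exponent / 2))
  re <- stats::rnorm(nf / 2 + 1); im <- stats::rnorm(nf / 2 + 1)
  spec <- complex(real = re * amp, imaginary = im * amp)
  spec[1] <- 0; spec[nf / 2 + 1] <- complex(real = re[nf / 2 + 1] * amp[nf / 2 + 1])
  full <- c(spec, Conj(rev(spec[2:(nf / 2)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# biphasic difference-of-Gaussians kernel sampled at `rate`, ~width_s span
dog_kernel <- function(rate, width_s) {
  tt <- seq(-width_s, width_s, by = 1 / rate)
  s1 <- width_s / 6; s2 <- width_s / 4
  k <- exp(-(tt + width_s / 8)^2 / (2 * s1^2)) -
    0.8 * exp(-(tt - width_s / 4)^2 / (2 * s2^2))
  k / max(abs(k))
}

# raised-cosine window of given width, peak 1 at centre
raised_cosine <- function(rate, width_s) {
  tt <- seq(-width_s / 2, width_s / 2, by = 1 / rate)
  0.5 * (1 + cos(2 * pi * tt / width_s))
}

# sum of a kernel placed at event sample indices
place_kernel <- function(n, centers_idx, kernel) {
  out <- numeric(n)
  half <- (length(kernel) - 1L) %/% 2L
  for (c0 in centers_idx) {
    i0 <- c0 - half; i1 <- i0 + length(kernel) - 1L
    k0 <- max(1L, 1L - i0 + 1L); k1 <- length(kernel) - max(0L, i1 - n)
    if (k0 > k1) next
    rng <- max(1L, i0):min(n, i1)
    out[rng] <- out[rng] + kernel[k0:k1]
  }
  out
}

#' Generate a synthetic session
#'
#' Builds, per channel, 1/f background noise plus band-limited noise
#' carriers in 16-28 Hz and 56-128 Hz whose amplitudes are multiplicatively
#' modulated around each event (raised-cosine window), plus an additive slow
#' biphasic transient; all event-locked terms are placed at the event time
#' plus a shared per-event jitter. Ground-truth labels are the unjittered
#' event times. Each channel carries its own effect topography (fixed
#' per-channel gains drawn once per session), as electrode grids see
#' event-related signals with channel-dependent amplitude -- without this,
#' common-average referencing would cancel any spatially uniform component.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `recording` (a [recording()]) and `events` (an
#'   [event_list()]).
#' @export
generate_session <- function(cfg, seed) {
  stopifnot(inherits(cfg, "SynthConfig"))
  events <- generate_events(cfg, seed)
  n <- round(cfg$duration_s * cfg$rate)
  set.seed(sub_seed(seed, 2L))
  jit <- stats::rnorm(length(events), 0, cfg$jitter_s)
  resp_idx <- round((as.numeric(events) + jit) * cfg$rate) + 1L

  mod_train <- place_kernel(n, resp_idx,
                            raised_cosine(cfg$rate, cfg$mod_width_s))
  lfc_idx <- round((as.numeric(events) + jit + cfg$lfc_effect$latency_s) *
                     cfg$rate) + 1L
  slow <- cfg$lfc_effect$amp * cfg$noise$level *
    place_kernel(n, lfc_idx, dog_kernel(cfg$rate, cfg$lfc_effect$width_s))

  # per-channel effect topography
  set.seed(sub_seed(seed, 3L))
  gain_lfc <- stats::rnorm(cfg$n_channels, 1, 0.5)
  gain_beta <- stats::runif(cfg$n_channels, 0.5, 1.5)
  gain_gamma <- stats::runif(cfg$n_channels, 0.5, 1.5)

  # The fractional effects are defined on the band amplitudes themselves, so
  # ALL in-band background content must carry the modulation: the background
  # is band-stopped in both effect bands and replaced by independent
  # band-limited carriers of matching spectral level, which are then
  # multiplied by the event-locked gain.
  w_beta <- c(16, 28) / (cfg$rate / 2)
  w_gamma <- c(56, min(128, cfg$rate / 2 * 0.98)) / (cfg$rate / 2)
  bp_beta <- signal::butter(4, w_beta, type = "pass")
  bp_gamma <- signal::butter(4, w_gamma, type = "pass")
  bs_beta <- signal::butter(4, w_beta, type = "stop")
  bs_gamma <- signal::butter(4, w_gamma, type = "stop")
  x <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    set.seed(sub_seed(seed, 10L + ch))
    bg <- pink_noise(n, cfg$rate, cfg$noise$exponent) * cfg$noise$level
    sd_beta <- stats::sd(signal::filter(bp_beta, bg))
    sd_gamma <- stats::sd(signal::filter(bp_gamma, bg))
    rest <- as.numeric(signal::filter(bs_gamma,
                                      as.numeric(signal::filter(bs_beta, bg))))
    cb <- as.numeric(signal::filter(bp_beta, pink_noise(n, cfg$rate,
                                                        cfg$noise$exponent)))
    cb <- cb / stats::sd(cb) * sd_beta
    cg <- as.numeric(signal::filter(bp_gamma, pink_noise(n, cfg$rate,
                                                         cfg$noise$exponent)))
    cg <- cg / stats::sd(cg) * sd_gamma
    g_beta <- pmax(0, 1 + cfg$beta_effect * gain_beta[ch] * mod_train)
    g_gamma <- pmax(0, 1 + cfg$gamma_effect * gain_gamma[ch] * mod_train)
    x[ch, ] <- rest + cb * g_beta + cg * g_gamma + slow * gain_lfc[ch]
  }
  list(recording = recording(x, cfg$rate), events = events)
}
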