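#' Define a fricative continuum
#'
#' A continuum is a set of `n_steps` noise-excited fricative stimuli whose
#' spectral envelope carries the category cue: three spectral peaks whose
#' amplitudes and bandwidths are linearly interpolated between the two
#' endpoint phonemes. Step 1 is the "sh"-like endpoint (low-frequency peak
#' emphasized) and step `n_steps` the "s"-like endpoint (high-frequency peak
#' emphasized). The fricative is followed by a steady vowel; a raised-cosine
#' envelope rises over the first `onset_ramp_fraction` of the fricative and
#' falls over the last `offset_ramp_fraction`.
#'
#' @param n_steps number of continuum steps (>= 2).
#' @param peak_centers three spectral peak center frequencies in Hz.
#' @param endpoint_amplitudes 3 x 2 matrix of per-peak amplitudes in dB above
#'   the noise floor; column 1 is the step-1 endpoint, column 2 the final step.
#' @param endpoint_bandwidths 3 x 2 matrix of per-peak FWHM bandwidths in Hz,
#'   same layout.
#' @param fricative_duration fricative duration in seconds (the study used
#'   0.100 s and 0.300 s).
#' @param vowel_duration vowel duration in seconds.
#' @param onset_ramp_fraction,offset_ramp_fraction fraction of the fricative
#'   over which the cosine envelope rises / falls; their sum must be <= 1.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `continuum_spec`.
#' @export
continuum_spec <- function(n_steps = 7,
                           peak_centers = c(2500, 3500, 6500),
                           endpoint_amplitudes = default_endpoint_amplitudes(),
                           endpoint_bandwidths = default_endpoint_bandwidths(),
                           fricative_duration = 0.300,
                           vowel_duration = 0.250,
                           onset_ramp_fraction = 0.75,
                           offset_ramp_fraction = 0.20,
                           sample_rate = 44100) {
  check_scalar(n_steps, "n_steps", lower = 2)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  if (length(peak_centers) != 3L || any(!is.finite(peak_centers)))
    stop("'peak_centers' must be three finite frequencies", call. = FALSE)
  if (any(peak_centers <= 0) || any(peak_centers >= sample_rate / 2))
    stop("'peak_centers' must lie in (0, sample_rate/2)", call. = FALSE)
  endpoint_amplitudes <- as.matrix(endpoint_amplitudes)
  endpoint_bandwidths <- as.matrix(endpoint_bandwidths)
  if (!all(dim(endpoint_amplitudes) == c(3L, 2L)))
    stop("'endpoint_amplitudes' must be a 3 x 2 matrix", call. = FALSE)
  if (!all(dim(endpoint_bandwidths) == c(3L, 2L)))
    stop("'endpoint_bandwidths' must be a 3 x 2 matrix", call. = FALSE)
  if (any(endpoint_bandwidths <= 0))
    stop("'endpoint_bandwidths' must be positive", call. = FALSE)
  check_scalar(fricative_duration, "fricative_duration", lower = 0, strict_lower = TRUE)
  check_scalar(vowel_duration, "vowel_duration", lower = 0)
  check_scalar(onset_ramp_fraction, "onset_ramp_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(offset_ramp_fraction, "offset_ramp_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (onset_ramp_fraction + offset_ramp_fraction > 1)
    stop("'onset_ramp_fraction' + 'offset_ramp_fraction' must be <= 1",
         call. = FALSE)
  structure(list(
    n_steps = as.integer(n_steps),
    peak_centers = as.numeric(peak_centers),
    endpoint_amplitudes = endpoint_amplitudes,
    endpoint_bandwidths = endpoint_bandwidths,
    fricative_duration = fricative_duration,
    vowel_duration = vowel_duration,
    onset_ramp_fraction = onset_ramp_fraction,
    offset_ramp_fraction = offset_ramp_fraction,
    sample_rate = sample_rate
  ), class = "continuum_spec")
}

# Default endpoints: step 1 emphasizes the 2500 Hz peak ("sh"-like), the last
# step emphasizes 6500 Hz ("s"-like). Values are configuration, not phonetic
# ground truth; rows follow peak_centers order.
#' @rdname continuum_spec
#' @export
default_endpoint_amplitudes <- function() {
  matrix(c(30, 6,
           22, 14,
           6, 30),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("p2500", "p3500", "p6500"), c("step1", "stepN")))
}

#' @rdname continuum_spec
#' @export
default_endpoint_bandwidths <- function() {
  matrix(c(800, 1000,
           900, 900,
           1500, 1000),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("p2500", "p3500", "p6500"), c("step1", "stepN")))
}

#' Interpolate the continuum steps
#'
#' Computes per-step spectral-peak parameters by arithmetic linear
#' interpolation between the endpoint amplitudes and bandwidths.
#'
#' @param spec a [continuum_spec()].
#' @return a data.frame with one row per step x peak and columns
#'   `step`, `peak`, `center_hz`, `amplitude_db`, `bandwidth_hz`.
#' @export
design_continuum <- function(spec) {
  stopifnot(inherits(spec, "continuum_spec"))
  k <- spec$n_steps
  frac <- if (k == 1L) 0 else (seq_len(k) - 1) / (k - 1)
  out <- expand.grid(peak = 1:3, step = seq_len(k))[, c("step", "peak")]
  out$center_hz <- spec$peak_centers[out$peak]
  a <- spec$endpoint_amplitudes
  b <- spec$endpoint_bandwidths
  out$amplitude_db <- a[cbind(out$peak, 1L)] * (1 - frac[out$step]) +
    a[cbind(out$peak, 2L)] * frac[out$step]
  out$bandwidth_hz <- b[cbind(out$peak, 1L)] * (1 - frac[out$step]) +
    b[cbind(out$peak, 2L)] * frac[out$step]
  out
}

# Gaussian-peak dB gain curve evaluated at frequencies f (Hz).
# bandwidth is the FWHM of each dB-domain Gaussian bump.
peak_gain_db <- function(f, centers, amplitudes_db, bandwidths_hz) {
  g <- numeric(length(f))
  for (i in seq_along(centers)) {
    sigma2 <- bandwidths_hz[i]^2 / (8 * log(2))
    g <- g + amplitudes_db[i] * exp(-(f - centers[i])^2 / (2 * sigma2))
  }
  g
}

# raised-cosine onset/offset envelope over n samples
cosine_envelope <- function(n, onset_frac, offset_frac) {
  env <- rep(1, n)
  n_on <- round(onset_frac * n)
  n_off <- round(offset_frac * n)
  if (n_on > 0) {
    i <- seq_len(n_on)
    env[i] <- 0.5 - 0.5 * cos(pi * (i - 1) / n_on)
  }
  if (n_off > 0) {
    i <- seq_len(n_off)
    env[n - n_off + i] <- 0.5 + 0.5 * cos(pi * i / n_off)
  }
  env
}

#' Synthesize one continuum stimulus
#'
#' Generates the fricative for one continuum step by imposing the step's
#' three-peak magnitude spectrum on white noise (FFT magnitude shaping),
#' applies the raised-cosine onset/offset envelope, and concatenates a vowel.
#' When no vowel waveform is supplied a steady synthetic vowel (harmonic
#' complex shaped by three formant resonances) is generated at
#' `spec$vowel_duration`. The result is RMS-normalized to `rms_level`.
#'
#' @param step integer continuum step index in `1:spec$n_steps`.
#' @param spec a [continuum_spec()].
#' @param vowel optional `phonocat_wave` to splice after the fricative; its
#'   sample rate must match `spec$sample_rate`.
#' @param seed integer seed for the noise excitation (required, so stimuli are
#'   reproducible).
#' @param rms_level target RMS amplitude of the full stimulus (digital
#'   full-scale units; presentation level is hardware-dependent and out of
#'   scope).
#' @return a `phonocat_wave`: list with `samples` (numeric vector) and
#'   `sample_rate`.
#' @export
synthesize_stimulus <- function(step, spec, vowel = NULL, seed, rms_level = 0.05) {
  stopifnot(inherits(spec, "continuum_spec"))
  check_scalar(step, "step", lower = 1, upper = spec$n_steps)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible synthesis", call. = FALSE)
  fric <- synthesize_fricative(step, spec, seed)$samples
  fs <- spec$sample_rate

  if (is.null(vowel)) {
    vow <- synth_vowel(spec$vowel_duration, fs)
  } else {
    stopifnot(inherits(vowel, "phonocat_wave"))
    if (!isTRUE(all.equal(vowel$sample_rate, fs)))
      stop("vowel sample rate does not match the continuum sample rate", call. = FALSE)
    vow <- vowel$samples
  }
  x <- c(fric, vow)
  x <- x * rms_level / sqrt(mean(x^2))
  structure(list(samples = x, sample_rate = fs), class = "phonocat_wave")
}

#' Synthesize the fricative portion only
#'
#' The spectrally shaped, envelope-ramped noise burst for one continuum step,
#' without the vowel and without RMS normalization. Useful for spectral
#' verification of the synthesis.
#'
#' @inheritParams synthesize_stimulus
#' @return a `phonocat_wave`.
#' @export
synthesize_fricative <- function(step, spec, seed) {
  stopifnot(inherits(spec, "continuum_spec"))
  check_scalar(step, "step", lower = 1, upper = spec$n_steps)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible synthesis", call. = FALSE)
  steps <- design_continuum(spec)
  st <- steps[steps$step == step, ]
  fs <- spec$sample_rate
  n <- round(spec$fricative_duration * fs)
  fric <- with_seed(seed, {
    noise <- stats::rnorm(n)
    shape_noise_spectrum(noise, fs, st$center_hz, st$amplitude_db, st$bandwidth_hz)
  })
  fric <- fric * cosine_envelope(n, spec$onset_ramp_fraction, spec$offset_ramp_fraction)
  structure(list(samples = fric, sample_rate = fs), class = "phonocat_wave")
}

# Impose a three-peak magnitude spectrum on a white-noise excitation by FFT
# magnitude shaping (gain applied symmetrically to conjugate frequencies).
shape_noise_spectrum <- function(noise, fs, centers, amplitudes_db, bandwidths_hz) {
  n <- length(noise)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2] so conjugate bins share the gain
  gain <- 10^(peak_gain_db(f, centers, amplitudes_db, bandwidths_hz) / 20)
  Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE)) / n
}

#' Synthetic steady vowel
#'
#' A harmonic complex at fundamental `f0` whose partial amplitudes are shaped
#' by three formant resonances (Gaussian dB gains) over a -6 dB/octave source
#' rolloff. Short 10 ms raised-cosine edges avoid onset/offset clicks. Used in
#' place of a natural vowel token when none is supplied.
#'
#' @param duration seconds.
#' @param sample_rate Hz.
#' @param f0 fundamental frequency, Hz.
#' @param formants formant center frequencies, Hz.
#' @param formant_bw formant FWHM bandwidths, Hz.
#' @param formant_gain_db formant peak gains, dB.
#' @return numeric vector of samples (unnormalized).
#' @export
synth_vowel <- function(duration, sample_rate, f0 = 110,
                        formants = c(710, 1100, 2540),
                        formant_bw = c(130, 160, 300),
                        formant_gain_db = c(30, 24, 18)) {
  n <- round(duration * sample_rate)
  if (n == 0L) return(numeric(0))
  t <- (seq_len(n) - 1) / sample_rate
  h <- seq_len(floor(min(5000, sample_rate / 2 - 1) / f0))
  fh <- h * f0
  amp_db <- -6 * log2(fh / f0) +
    peak_gain_db(fh, formants, formant_gain_db, formant_bw)
  amp <- 10^(amp_db / 20)
  x <- numeric(n)
  for (i in seq_along(h)) x <- x + amp[i] * sin(2 * pi * fh[i] * t)
  edge <- min(round(0.010 * sample_rate), floor(n / 2))
  x * cosine_envelope(n, edge / n, edge / n)
}

#' Estimate spectral peak frequencies of a waveform
#'
#' Welch-averaged power spectrum (Hann-windowed overlapping segments) followed
#' by peak picking on the dB spectrum. Returns the frequencies of local maxima
#' at least `min_rel_db` below the global maximum, separated by at least
#' `min_separation_hz`.
#'
#' @param wave a `phonocat_wave` or numeric vector of samples.
#' @param sample_rate required when `wave` is a bare numeric vector.
#' @param nfft segment length (power of two); the analysis bin width is
#'   `sample_rate / nfft`.
#' @param refine_window_hz half-width of the quadratic-fit window used to
#'   refine each peak frequency below bin resolution.
#' @param min_rel_db peaks more than this many dB below the strongest peak are
#'   ignored.
#' @param min_separation_hz minimum spacing between reported peaks.
#' @return data.frame with columns `freq_hz` and `power_db`, sorted by
#'   frequency, plus attribute `bin_width_hz`.
#' @export
estimate_spectral_peaks <- function(wave, sample_rate = NULL, nfft = 512,
                                    min_rel_db = 15, min_separation_hz = 500,
                                    refine_window_hz = 300) {
  if (inherits(wave, "phonocat_wave")) {
    x <- wave$samples
    fs <- wave$sample_rate
  } else {
    x <- as.numeric(wave)
    if (is.null(sample_rate)) stop("'sample_rate' required", call. = FALSE)
    fs <- sample_rate
  }
  psd <- welch_psd(x, nfft)
  # Daniell smoothing (7-bin moving average) knocks down the periodogram
  # ripple that is not removed by segment averaging alone; symmetric peaks
  # keep their center
  sm <- stats::filter(psd$power, rep(1 / 7, 7), sides = 2)
  keep <- !is.na(sm)
  db <- 10 * log10(as.numeric(sm[keep]) + .Machine$double.xmin)
  freq <- psd$freq_hz[keep] * fs
  pk <- pracma::findpeaks(db, minpeakheight = max(db) - min_rel_db,
                          minpeakdistance = max(1L, round(min_separation_hz / (fs / nfft))))
  if (is.null(pk)) return(structure(data.frame(freq_hz = numeric(0), power_db = numeric(0)),
                                    bin_width_hz = fs / nfft))
  ord <- order(pk[, 2])
  idx <- pk[ord, 2]
  # refine each peak by a quadratic fit of the dB spectrum around the coarse
  # maximum: the raw argmax of a wide peak wobbles by a bin under the
  # periodogram ripple, the fitted vertex averages it out
  refined <- vapply(idx, function(i) {
    win <- which(abs(freq - freq[i]) <= refine_window_hz)
    if (length(win) < 5) return(freq[i])
    co <- stats::coef(stats::lm(db[win] ~ freq[win] + I(freq[win]^2)))
    if (!is.finite(co[3]) || co[3] >= 0) return(freq[i])
    vertex <- -co[2] / (2 * co[3])
    if (abs(vertex - freq[i]) > refine_window_hz) freq[i] else vertex
  }, numeric(1))
  structure(data.frame(freq_hz = refined, power_db = pk[ord, 1]),
            bin_width_hz = fs / nfft)
}

# Welch periodogram: Hann window, 50% overlap; freq_hz column is cycles/sample.
welch_psd <- function(x, nfft) {
  n <- length(x)
  if (n < nfft) nfft <- 2^floor(log2(n))
  hop <- nfft %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  starts <- seq(1, n - nfft + 1, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * win
    X <- stats::fft(seg)[seq_len(nfft %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  list(freq_hz = (seq_len(nfft %/% 2 + 1) - 1) / nfft,
       power = acc / (length(starts) * sum(win^2)))
}
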