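#' @title Acoustic front-end
#' @description The four preprocessing steps applied to every 60-second
#'   recording segment before recognition: (1) resampling to 8 kHz,
#'   (2) 5th-order Butterworth high-pass filtering at 500 Hz,
#'   (3) non-stationary noise suppression by spectral gating, and
#'   (4) conversion to a 64-band log-mel spectrogram at 100 frames/s.
#' @name audiofront
NULL

#' Front-end configuration
#'
#' @param target_rate Working sampling rate after resampling, Hz.
#' @param hp_order,hp_cutoff Butterworth high-pass order and cutoff (Hz).
#' @param n_mels Number of mel filters.
#' @param mel_fmin,mel_fmax Mel filterbank frequency range, Hz. The top edge
#'   is clamped to the post-resampling Nyquist frequency; the nominal 8 kHz
#'   upper edge exceeds the 4 kHz Nyquist at an 8 kHz working rate, and the
#'   clamp resolves that without changing the filter count.
#' @param frames_per_second Spectrogram frame rate.
#' @param window_s STFT analysis window length, seconds (Hann window).
#' @param gate Spectral-gating parameters: `percentile` of the short-time
#'   magnitude used as the per-band noise floor (estimated over `block_s`
#'   second blocks), `threshold_db` above the floor for a cell to count as
#'   signal, `gain_db` attenuation applied below the gate, and `smooth_t` /
#'   `smooth_f` mask smoothing extents (frames / bands).
#' @return List of class `frontend_config`.
#' @export
frontend_config <- function(target_rate = 8000, hp_order = 5,
                            hp_cutoff = 500, n_mels = 64, mel_fmin = 50,
                            mel_fmax = 8000, frames_per_second = 100,
                            window_s = 0.025,
                            gate = list(percentile = 0.2, threshold_db = 20,
                                        gain_db = -40, smooth_t = 3,
                                        smooth_f = 3, block_s = 2)) {
  stopifnot(hp_cutoff < target_rate / 2,
            1000 %% frames_per_second == 0 ||
              target_rate %% frames_per_second == 0)
  structure(list(target_rate = target_rate, hp_order = hp_order,
                 hp_cutoff = hp_cutoff, n_mels = n_mels,
                 mel_fmin = mel_fmin, mel_fmax = mel_fmax,
                 frames_per_second = frames_per_second,
                 window_s = window_s, gate = gate),
            class = "frontend_config")
}

# ---- resampling -------------------------------------------------------------

#' Resample audio with anti-aliasing
#'
#' Polyphase rational-ratio resampling (FIR anti-aliasing filter, via
#' `signal::resample`). Duration is preserved to within one sample.
#'
#' @param wave Numeric samples.
#' @param from,to Source and target sampling rates, Hz.
#' @return Resampled numeric vector (empty input gives empty output).
#' @export
resample_audio <- function(wave, from, to) {
  stopifnot(from > 0, to > 0)
  if (!length(wave)) return(numeric(0))
  if (from == to) return(wave)
  g <- gcd_int(round(from), round(to))
  p <- round(to) / g
  q <- round(from) / g
  y <- if (p == 1) decimate_fir(wave, q) else signal::resample(wave, p, q)
  n_target <- round(length(wave) * to / from)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  else if (length(y) < n_target) y <- c(y, numeric(n_target - length(y)))
  as.numeric(y)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Polyphase FIR decimation by an integer factor q: Kaiser-windowed linear-
# phase low-pass (cutoff 0.45 fs_out), evaluated only at the kept output
# instants. Zero-phase alignment via the n/2 group delay.
decimate_fir <- function(x, q) {
  n_taps <- 12L * q  # even order -> integer group delay
  h <- as.numeric(signal::fir1(n_taps, 0.9 / q,
                               window = signal::kaiser(n_taps + 1, 7.85)))
  m <- ceiling(length(x) / q)
  p <- (seq_len(m) - 1L) * q + 1L + n_taps %/% 2L
  y <- numeric(m)
  for (k in 0:n_taps) {
    idx <- p - k
    ok <- idx >= 1L & idx <= length(x)
    y[ok] <- y[ok] + h[k + 1L] * x[idx[ok]]
  }
  y
}

# ---- high-pass filter -------------------------------------------------------

#' Butterworth high-pass filter
#'
#' Maximally-flat 5th-order (by default) high-pass with -3 dB point at the
#' cutoff. `zero_phase = TRUE` (the pipeline default) applies the filter
#' forward and backward, avoiding group-delay smearing of frame labels at
#' the cost of doubling the stop-band attenuation in dB; `FALSE` gives the
#' plain forward pass with the textbook magnitude response.
#'
#' @param wave Numeric samples.
#' @param sample_rate Sampling rate, Hz.
#' @param order Filter order.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist.
#' @param zero_phase Forward-backward filtering if `TRUE`.
#' @return Filtered samples, same length as input.
#' @export
highpass <- function(wave, sample_rate, order = 5, cutoff = 500,
                     zero_phase = TRUE) {
  if (cutoff >= sample_rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below Nyquist (",
         sample_rate / 2, " Hz)")
  if (!length(wave)) return(numeric(0))
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "high")
  if (zero_phase) as.numeric(signal::filtfilt(bf, wave))
  else as.numeric(signal::filter(bf, wave))
}

# ---- STFT helpers -----------------------------------------------------------

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Short-time Fourier transform: complex (nfft/2+1) x n_frames matrix, frame
# t starting at sample (t-1)*hop + 1, end-padded with zeros.
stft <- function(x, win, hop, nfft = length(win)) {
  nw <- length(win)
  n_frames <- max(1L, ceiling(length(x) / hop))
  need <- (n_frames - 1L) * hop + nw
  if (length(x) < need) x <- c(x, numeric(need - length(x)))
  idx <- outer(seq_len(nw), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = nw) * win
  if (nfft > nw) frames <- rbind(frames, matrix(0, nfft - nw, n_frames))
  X <- stats::mvfft(frames)
  X[seq_len(nfft / 2 + 1), , drop = FALSE]
}

# Inverse STFT by weighted overlap-add (synthesis window = analysis window,
# normalized by the summed squared window).
istft <- function(X, win, hop, n_out) {
  nfft <- 2L * (nrow(X) - 1L)
  nw <- length(win)
  n_frames <- ncol(X)
  full <- rbind(X, Conj(X[(nfft / 2):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nfft
  frames <- frames[seq_len(nw), , drop = FALSE] * win
  y <- numeric((n_frames - 1L) * hop + nw)
  norm <- numeric(length(y))
  w2 <- win^2
  for (t in seq_len(n_frames)) {
    i <- (t - 1L) * hop
    y[i + seq_len(nw)] <- y[i + seq_len(nw)] + frames[, t]
    norm[i + seq_len(nw)] <- norm[i + seq_len(nw)] + w2
  }
  ok <- norm > 1e-8
  y[ok] <- y[ok] / norm[ok]
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

# ---- spectral gating --------------------------------------------------------

#' Non-stationary noise suppression by spectral gating
#'
#' Estimates a per-band, time-varying noise floor as a running percentile of
#' the short-time spectral magnitude (block-wise over `block_s`-second
#' blocks, linearly interpolated between block centers). Time-frequency
#' cells whose magnitude does not exceed the floor by `threshold_db` are
#' attenuated by `gain_db` through a smoothed soft mask; cells above the
#' gate pass essentially unchanged. Output length equals input length.
#'
#' @param wave Numeric samples.
#' @param sample_rate Sampling rate, Hz.
#' @param gate Parameter list, see [frontend_config()].
#' @return Noise-suppressed samples.
#' @export
spectral_gate <- function(wave, sample_rate,
                          gate = frontend_config()$gate) {
  if (!length(wave)) return(numeric(0))
  nfft <- 256L
  hop <- 64L
  win <- hann_window(nfft)
  pad <- nfft
  x <- c(numeric(pad), wave, numeric(pad))
  X <- stft(x, win, hop, nfft)
  A <- Mod(X)
  n_frames <- ncol(X)
  fpb <- max(1L, round(gate$block_s * sample_rate / hop))
  n_blocks <- max(1L, ceiling(n_frames / fpb))
  centers <- pmin((seq_len(n_blocks) - 0.5) * fpb, n_frames)
  floor_blocks <- matrix(0, nrow(A), n_blocks)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * fpb + 1L):min(b * fpb, n_frames)
    floor_blocks[, b] <- apply(A[, cols, drop = FALSE], 1, quantile,
                               probs = gate$percentile, names = FALSE)
  }
  nf <- if (n_blocks == 1) {
    matrix(floor_blocks[, 1], nrow(A), n_frames)
  } else {
    t(apply(floor_blocks, 1, function(r)
      approx(centers, r, xout = seq_len(n_frames), rule = 2)$y))
  }
  mask <- (A > nf * 10^(gate$threshold_db / 20)) * 1
  # pass-preserving smoothing: cells above the gate always keep unit gain,
  # the box-smoothed mask only feathers the pass region outward
  mask_s <- pmax(mask, smooth_mask(mask, gate$smooth_f, gate$smooth_t))
  g <- 10^(gate$gain_db / 20)
  gain <- g + (1 - g) * mask_s
  y <- istft(X * gain, win, hop, length(x))
  y[pad + seq_along(wave)]
}

# Box smoothing of a 0/1 mask over (bands x frames), renormalized so that
# interior cells fully surrounded by signal keep gain 1.
smooth_mask <- function(mask, kf, kt) {
  if (kf <= 1 && kt <= 1) return(mask)
  out <- matrix(0, nrow(mask), ncol(mask))
  cnt <- matrix(0, nrow(mask), ncol(mask))
  hf <- (kf - 1) %/% 2
  ht <- (kt - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  for (df in -hf:hf) for (dt in -ht:ht) {
    r_src <- max(1, 1 - df):min(nr, nr - df)
    c_src <- max(1, 1 - dt):min(nc, nc - dt)
    out[r_src + df, c_src + dt] <- out[r_src + df, c_src + dt] +
      mask[r_src, c_src]
    cnt[r_src + df, c_src + dt] <- cnt[r_src + df, c_src + dt] + 1
  }
  out / cnt
}

# ---- mel filterbank ---------------------------------------------------------

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters with HTK mel spacing between `fmin` and
#' `min(fmax, sample_rate/2)`, unit peak.
#'
#' @param n_mels Number of filters.
#' @param nfft FFT size.
#' @param sample_rate Sampling rate, Hz.
#' @param fmin,fmax Frequency range, Hz.
#' @return `n_mels x (nfft/2 + 1)` matrix.
#' @export
mel_filterbank <- function(n_mels, nfft, sample_rate, fmin = 50,
                           fmax = 8000) {
  fmax <- min(fmax, sample_rate / 2)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2))
  bins <- (0:(nfft / 2)) * sample_rate / nfft
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bins - lo) / (ce - lo)
    down <- (hi - bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Center frequencies of the mel filterbank, Hz
#' @inheritParams mel_filterbank
#' @return Numeric vector of length `n_mels`.
#' @export
mel_centers <- function(n_mels, sample_rate, fmin = 50, fmax = 8000) {
  fmax <- min(fmax, sample_rate / 2)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2))
  edges[2:(n_mels + 1)]
}

# ---- log-mel spectrogram ----------------------------------------------------

#' Log-mel spectrogram
#'
#' Frames the signal with a 25 ms Hann window at `frames_per_second` hops,
#' takes the power spectrum (FFT size 256 at 8 kHz), applies the mel
#' filterbank and compresses with `log(x + 1e-10)`. The frame count contract
#' is exact: a `d`-second input yields `round(d * frames_per_second)` frames
#' (minimum 1, with zero padding), so a 60 s segment always gives a
#' 6000 x 64 matrix.
#'
#' @param wave Samples at `config$target_rate`.
#' @param config A [frontend_config()].
#' @return `frames x n_mels` matrix of log energies, with attributes
#'   `frame_rate` and `sample_rate`.
#' @export
logmel <- function(wave, config = frontend_config()) {
  fs <- config$target_rate
  hop <- fs / config$frames_per_second
  stopifnot(hop == round(hop))
  nw <- round(config$window_s * fs)
  nfft <- 2^ceiling(log2(nw))
  n_frames <- max(1L, as.integer(round(length(wave) / hop)))
  need <- (n_frames - 1L) * hop + nw
  if (length(wave) < need) wave <- c(wave, numeric(need - length(wave)))
  win <- hann_window(nw)
  idx <- outer(seq_len(nw), (seq_len(n_frames) - 1L) * as.integer(hop), "+")
  frames <- matrix(wave[idx], nrow = nw) * win
  if (nfft > nw) frames <- rbind(frames, matrix(0, nfft - nw, n_frames))
  P <- Mod(stats::mvfft(frames)[seq_len(nfft / 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(config$n_mels, nfft, fs, config$mel_fmin,
                       config$mel_fmax)
  M <- log(fb %*% P + 1e-10)
  out <- t(M)
  attr(out, "frame_rate") <- config$frames_per_second
  attr(out, "sample_rate") <- fs
  out
}

# ---- full chain -------------------------------------------------------------

#' Full acoustic front-end
#'
#' Resample to the working rate, high-pass filter, spectral-gate, and
#' convert to a log-mel spectrogram. A pure function of (samples, config).
#'
#' @param wave Numeric samples.
#' @param sample_rate Input sampling rate, Hz.
#' @param config A [frontend_config()].
#' @param zero_phase Filter direction for the high-pass stage.
#' @return Log-mel matrix as from [logmel()].
#' @export
frontend <- function(wave, sample_rate, config = frontend_config(),
                     zero_phase = TRUE) {
  x <- resample_audio(wave, sample_rate, config$target_rate)
  x <- highpass(x, config$target_rate, config$hp_order, config$hp_cutoff,
                zero_phase = zero_phase)
  x <- spectral_gate(x, config$target_rate, config$gate)
  logmel(x, config)
}
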