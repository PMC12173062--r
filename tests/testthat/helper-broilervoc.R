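# Shared helpers for the test suite. Fixtures are all generated in code.

# A random, properly normalized probability raster (rows sum to 1).
random_raster <- function(n_rows, seed = NULL, sharp = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rexp(n_rows * 6, if (sharp) 0.2 else 1), n_rows, 6)
  x <- x / rowSums(x)
  colnames(x) <- MODEL_CLASSES
  x
}

# Dominant-frequency trajectory of a clean waveform, via STFT peak picking
# (independent of the synthesis path: plain spectrogram argmax).
dominant_freq_track <- function(wave, sample_rate, nfft = 1024,
                                hop = 256) {
  n_frames <- max(1, floor((length(wave) - nfft) / hop) + 1)
  freqs <- (0:(nfft / 2)) * sample_rate / nfft
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / nfft)
  sapply(seq_len(n_frames), function(t) {
    seg <- wave[(t - 1) * hop + seq_len(nfft)] * win
    spec <- Mod(fft(seg))[seq_len(nfft / 2 + 1)]
    freqs[which.max(spec)]
  })
}

# Median fundamental over the voiced part of a call.
measure_f0 <- function(event, sample_rate = 48000) {
  w <- synth_call(event, sample_rate)
  tr <- dominant_freq_track(w, sample_rate)
  amp <- sapply(seq_along(tr), function(t) {
    seg <- w[(t - 1) * 256 + seq_len(1024)]
    sqrt(mean(seg^2))
  })
  median(tr[amp > 0.3 * max(amp)])
}

# Tiny two-class training set + model, cached per session for reuse across
# recognizer unit tests.
tiny_model_env <- new.env()
get_tiny_trained <- function() {
  if (is.null(tiny_model_env$model)) {
    ds <- make_training_set(
      n_per_class = 24, classes = c("background", "DC"),
      snippet_s = 1.2, seed = 31)
    m <- build_model(recognizer_config(seed = 5, epochs = 4))
    tiny_model_env$model <- train(m, ds)
    tiny_model_env$holdout <- make_training_set(
      n_per_class = 10, classes = c("background", "DC"),
      snippet_s = 1.2, seed = 77)
  }
  list(model = tiny_model_env$model, holdout = tiny_model_env$holdout)
}
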