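#' Build a labeled training set from continuous synthetic soundscapes
#'
#' Synthesizes one-minute soundscapes (each with its own bird age drawn
#' uniformly from `age_range` and a busy constant-rate profile), runs them
#' through the acoustic front-end, and slices the log-mel output into
#' fixed-length windows whose 240 ms rows carry the ground-truth
#' frame-midpoint labels. Training windows therefore contain calls at
#' every phase relative to the frame grid, call-adjacent background, and
#' inter-syllable gaps - the same distribution the recognizer sees when
#' scanning continuous recordings.
#'
#' @param n_minutes Number of one-minute soundscapes.
#' @param rates Named per-type rates (s/min) of the training profile;
#'   defaults give roughly balanced 240 ms label rows across classes with
#'   about half the rows background.
#' @param window_s Window length in seconds (multiple of 0.24).
#' @param snr_db,sample_rate,background,age_range As in
#'   [soundscape_config()] / [make_training_set()].
#' @param allow_overlap Overlap policy of the training soundscapes.
#' @param seed RNG seed; fully determines the set.
#' @return List of examples (`spect`, `labels`, `age_days`).
#' @export
make_soundscape_training_set <- function(
    n_minutes = 40,
    rates = c(SP = 8, PN = 8, DC = 6, W = 4, OV = 4),
    window_s = 2.4, snr_db = 20, sample_rate = 48000,
    background = "white", age_range = c(1, 42),
    allow_overlap = FALSE, seed = 1L) {
  stopifnot(abs(window_s / PRED_FRAME_S -
                  round(window_s / PRED_FRAME_S)) < 1e-9)
  prof <- diurnal_profile(as.list(rates))
  rows_per_win <- round(window_s / PRED_FRAME_S)
  frames_per_win <- rows_per_win * 24L
  out <- list()
  ages <- with_seed(seed, sample(seq(age_range[1], age_range[2]),
                                 n_minutes, replace = TRUE))
  for (m in seq_len(n_minutes)) {
    cfg <- soundscape_config(60, prof, sample_rate = sample_rate,
                             age_days = ages[m], snr_db = snr_db,
                             background = background,
                             seed = seed + 131L * m,
                             allow_overlap = allow_overlap)
    sc <- synth_soundscape(cfg)
    spect <- frontend(sc$wave, sample_rate)
    labels <- sc$truth$frame_labels
    n_win <- nrow(spect) %/% frames_per_win
    for (w in seq_len(n_win)) {
      fr <- (w - 1L) * frames_per_win + seq_len(frames_per_win)
      rw <- (w - 1L) * rows_per_win + seq_len(rows_per_win)
      out[[length(out) + 1L]] <-
        list(spect = spect[fr, , drop = FALSE], labels = labels[rw],
             age_days = ages[m])
    }
  }
  out
}

#' Build a labeled training set from synthetic calls
#'
#' Generates short audio snippets, each containing background noise and (for
#' the call classes) one synthetic call at a uniformly random position,
#' processes them through the acoustic front-end, and labels every 240 ms
#' output step by the frame-midpoint rule. Because call placement is
#' unconditioned, snippets of short call types can yield background-only
#' label rows - exactly as in continuous recordings - and the inverse
#' frequency class weights in [train()] compensate for the imbalance.
#'
#' @param n_per_class Snippets generated per class (a named vector can give
#'   per-class counts, e.g. extra background snippets).
#' @param classes Classes to include (default all six).
#' @param snippet_s Snippet length in seconds; must be a multiple of 0.24.
#'   The default 2.4 s exceeds the network's receptive field, so central
#'   output steps see full acoustic context as they do in 60 s segments.
#' @param calls_per_snippet Range of call counts placed in one snippet of a
#'   call class; short types (SP, PN) use `3:6` by default so their 240 ms
#'   label rows are not vanishingly rare, longer types `1:2`.
#' @param snr_db Per-call SNR over the background, dB.
#' @param age_range Integer range of bird ages (days) sampled per snippet.
#' @param sample_rate Synthesis rate, Hz.
#' @param fe_config Front-end configuration.
#' @param background Background noise type.
#' @param seed RNG seed; fully determines the dataset.
#' @return List of examples (`spect`, `labels`, `age_days`), usable with
#'   [train()] and [evaluate()].
#' @export
make_training_set <- function(n_per_class = 120,
                              classes = MODEL_CLASSES,
                              snippet_s = 2.4, snr_db = 20,
                              age_range = c(1, 42),
                              sample_rate = 48000,
                              fe_config = frontend_config(),
                              background = "white",
                              calls_per_snippet = NULL, seed = 1L) {
  stopifnot(all(classes %in% MODEL_CLASSES),
            abs(snippet_s / PRED_FRAME_S -
                  round(snippet_s / PRED_FRAME_S)) < 1e-9)
  if (length(n_per_class) == 1)
    n_per_class <- setNames(rep(n_per_class, length(classes)), classes)
  with_seed(seed, {
    n_samp <- round(snippet_s * sample_rate)
    out <- vector("list", sum(n_per_class[classes]))
    k <- 0
    for (cls in classes) {
      for (r in seq_len(n_per_class[[cls]])) {
        age <- sample(seq(age_range[1], age_range[2]), 1)
        bg <- synth_background(background, n_samp, sample_rate)
        if (cls == "background") {
          ev <- data.frame(type = character(0), onset = numeric(0),
                           duration = numeric(0), level_db = numeric(0))
          call_rms <- 0.05  # reference level for noise scaling
          wave <- bg * (call_rms / 10^(snr_db / 20) /
                          band_rms(bg, sample_rate))
        } else {
          ncalls <- if (!is.null(calls_per_snippet)) {
            sample(calls_per_snippet, 1)
          } else if (mean_call_duration(cls) < 0.25) {
            sample(3:6, 1)
          } else sample(1:2, 1)
          evs <- vector("list", ncalls)
          busy <- matrix(numeric(0), 0, 2)
          for (ci in seq_len(ncalls)) {
            e <- sample_call_event(cls, onset = 0, age_days = age)
            lo <- 0.05
            hi <- max(lo + 0.01, snippet_s - e$duration - 0.05)
            # up to 10 placement attempts avoiding within-snippet overlap
            for (try in 1:10) {
              e$onset <- runif(1, lo, hi)
              if (!nrow(busy) ||
                  all(e$onset + e$duration <= busy[, 1] |
                        e$onset >= busy[, 2])) break
            }
            busy <- rbind(busy, c(e$onset, e$onset + e$duration))
            evs[[ci]] <- e
          }
          ev <- do.call(rbind, evs)
          call_rms <- mean(0.05 * 10^(ev$level_db / 20))
          wave <- bg * (call_rms / 10^(snr_db / 20) /
                          band_rms(bg, sample_rate))
          for (ci in seq_len(nrow(ev))) {
            w <- synth_call(ev[ci, ], sample_rate)
            i0 <- round(ev$onset[ci] * sample_rate)
            idx <- i0 + seq_along(w)
            ok <- idx >= 1 & idx <= n_samp
            wave[idx[ok]] <- wave[idx[ok]] + w[ok]
          }
        }
        spect <- frontend(wave, sample_rate, fe_config)
        labels <- frame_labels_from_events(ev, snippet_s)
        t_out <- nrow(spect) %/% 24
        k <- k + 1
        out[[k]] <- list(spect = spect, labels = labels[seq_len(t_out)],
                         age_days = age)
      }
    }
    out
  })
}
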