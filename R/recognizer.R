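#' @title Fully-convolutional broiler vocalization recognizer
#' @description An eleven-layer two-dimensional convolutional stack over
#'   (time x mel) followed by a one-dimensional convolutional head, about
#'   one million trainable parameters in total. Temporal strides compose to
#'   a factor-24 downsampling, so the network emits one prediction per
#'   240 ms of audio at the 100 frames/s input rate: six normalized class
#'   scores (background, DC, PN, W, SP, OV) that sum to one, plus an
#'   auxiliary age estimate in days. The network is fully convolutional:
#'   any input length yields `floor(frames / 24)` output steps.
#' @name recognizer
NULL

#' Recognizer configuration
#'
#' The default architecture uses 3x3 kernels throughout, batch
#' normalization and ReLU after every convolution, mel strides halving the
#' 64 bands down to 1 over the first six layers, and temporal strides
#' (2, 2, 2, 3) spread over the stack.
#'
#' @param channels Output channels of the 11 conv2d layers.
#' @param strides_t,strides_m Temporal and mel strides per layer; the
#'   product of `strides_t` must be 24 (one output per 240 ms) and the
#'   product of `strides_m` must be 64 (mel dimension reduced to 1).
#' @param seed Integer seed for weight initialization and training.
#' @param epochs,batch_size,learning_rate Training schedule.
#' @param two_phase If `TRUE`, train the head alone for `phase1_epochs`
#'   first, then all layers at `learning_rate / 5` (a transfer-learning
#'   style schedule; with from-scratch initialization single-phase is the
#'   default).
#' @param phase1_epochs Head-only epochs when `two_phase` is set.
#' @param age_loss_weight Weight of the auxiliary L1 age loss (days).
#' @return List of class `recognizer_config`.
#' @export
recognizer_config <- function(
    channels = c(16, 16, 32, 32, 64, 64, 128, 128, 128, 192, 192),
    strides_t = c(1, 2, 1, 2, 1, 2, 1, 1, 3, 1, 1),
    strides_m = c(2, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1),
    seed = 1L, epochs = 8, batch_size = 32, learning_rate = 1e-3,
    two_phase = FALSE, phase1_epochs = 2, age_loss_weight = 0.1) {
  stopifnot(length(channels) == 11, length(strides_t) == 11,
            length(strides_m) == 11,
            prod(strides_t) == 24, prod(strides_m) == 64)
  structure(list(channels = channels, strides_t = strides_t,
                 strides_m = strides_m, n_classes = 6L,
                 seed = as.integer(seed),
                 training = list(epochs = epochs, batch_size = batch_size,
                                 learning_rate = learning_rate,
                                 two_phase = two_phase,
                                 phase1_epochs = phase1_epochs,
                                 age_loss_weight = age_loss_weight)),
            class = "recognizer_config")
}

count_parameters_config <- function(config) {
  cin <- c(1, config$channels[-11])
  conv <- sum(9 * cin * config$channels + 3 * config$channels)  # W + b + BN
  head <- 3 * config$channels[11] * 7 + 7
  conv + head
}

#' Build an untrained recognizer
#'
#' Initializes all convolution weights (He-normal), biases, and batch-norm
#' parameters from the config seed. The trainable-parameter count is
#' enforced at build time: configurations outside `[0.96e6, 1.44e6]`
#' (approximately 1.2 million, +/- 20%) are rejected with the actual count.
#'
#' @param config A [recognizer_config()].
#' @return Object of class `broiler_recognizer`.
#' @export
build_model <- function(config = recognizer_config()) {
  n_par <- count_parameters_config(config)
  if (n_par < 0.96e6 || n_par > 1.44e6)
    stop("trainable parameter count ", n_par,
         " outside tolerance [960000, 1440000]")
  with_seed(config$seed, {
    cin <- c(1, config$channels[-11])
    layers <- vector("list", 11)
    for (i in 1:11) {
      fan_in <- 9 * cin[i]
      layers[[i]] <- list(
        W = matrix(rnorm(config$channels[i] * fan_in,
                         sd = sqrt(2 / fan_in)),
                   config$channels[i], fan_in),
        b = numeric(config$channels[i]),
        gamma = rep(1, config$channels[i]),
        beta = numeric(config$channels[i]),
        rmean = numeric(config$channels[i]),
        rvar = rep(1, config$channels[i]),
        stride_t = as.integer(config$strides_t[i]),
        stride_m = as.integer(config$strides_m[i]))
    }
    ch <- config$channels[11]
    head <- list(W = matrix(rnorm(7 * 3 * ch, sd = sqrt(2 / (3 * ch))),
                            7, 3 * ch),
                 b = numeric(7))
    structure(list(layers = layers, head = head, config = config,
                   input_shift = 18, input_scale = 6, trained = FALSE),
              class = "broiler_recognizer")
  })
}

#' Number of trainable parameters of a built model
#' @param model A `broiler_recognizer`.
#' @return Integer parameter count (convolution weights, biases, batch-norm
#'   scale/shift, head weights).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(L)
    length(L$W) + length(L$b) + length(L$gamma) + length(L$beta), 0)) +
    length(model$head$W) + length(model$head$b)
}

# Flatten a frames x mels matrix into the C x (T*M) layout the C++ core
# expects (normalized), for one or more equal-sized examples.
spect_to_input <- function(model, spects) {
  if (is.matrix(spects)) spects <- list(spects)
  cols <- lapply(spects, function(s) as.vector(t(s)))
  matrix((unlist(cols) + model$input_shift) / model$input_scale, nrow = 1)
}

#' Run the recognizer over a log-mel spectrogram
#'
#' A pure function of (model, spectrogram): emits `floor(frames / 24)`
#' prediction steps, each with six probability scores summing to one and an
#' age estimate in days. Inputs shorter than 24 frames give an empty raster.
#'
#' @param model A trained (or built) `broiler_recognizer`.
#' @param spect `frames x 64` log-mel matrix (see [logmel()]).
#' @param start_clock Optional start time of the segment, seconds since
#'   day-0 midnight (propagated to the raster for wall-clock alignment).
#' @return Object of class `prob_raster`: list with `scores`
#'   (`T_out x 6` matrix, columns `MODEL_CLASSES`), `age_estimate` (days),
#'   `frame_duration` (0.24 s), `start_clock`.
#' @export
infer <- function(model, spect, start_clock = 0) {
  stopifnot(inherits(model, "broiler_recognizer"), is.matrix(spect))
  n_frames <- nrow(spect)
  if (n_frames < 24) {
    return(structure(list(
      scores = matrix(numeric(0), 0, 6,
                      dimnames = list(NULL, MODEL_CLASSES)),
      age_estimate = numeric(0), frame_duration = PRED_FRAME_S,
      start_clock = start_clock), class = "prob_raster"))
  }
  x <- spect_to_input(model, spect)
  out <- cpp_net_infer(model$layers, model$head, x, n_frames,
                       ncol(spect), 1L)
  scores <- out$scores
  colnames(scores) <- MODEL_CLASSES
  structure(list(scores = scores, age_estimate = as.numeric(out$age),
                 frame_duration = PRED_FRAME_S, start_clock = start_clock),
            class = "prob_raster")
}

# ---- training ---------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(layers = lapply(model$layers, function(L)
         list(m = zero_like(L[c("W", "b", "gamma", "beta")]),
              v = zero_like(L[c("W", "b", "gamma", "beta")]))),
       head = list(m = zero_like(model$head), v = zero_like(model$head)),
       t = 0)
}

adam_update <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8,
                        t = 1) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = st$m, v = st$v)
}

#' Train the recognizer on a labeled dataset
#'
#' Minimizes class cross-entropy (with inverse-frequency class weights;
#' background dominates any realistic soundscape) plus `age_loss_weight`
#' times an L1 age-regression loss, using Adam. Fully seeded: identical
#' seeds, data and thread configuration give identical final parameters.
#'
#' @param model A built `broiler_recognizer`.
#' @param dataset List of examples, each a list with elements `spect`
#'   (`frames x 64` log-mel matrix; all examples must share one frame
#'   count), `labels` (character vector of per-240 ms classes from
#'   `MODEL_CLASSES`, length `floor(frames / 24)`), and `age_days`.
#' @param epochs,batch_size,learning_rate Optional overrides of the
#'   config's training schedule.
#' @param weight_exponent Exponent of the tempered inverse-frequency class
#'   weights (`1/n^e`); 0.5 by default, 1 for full inverse frequency.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with a `history` data frame (per-epoch class
#'   and age losses) attached as `model$history`.
#' @export
train <- function(model, dataset, epochs = NULL, batch_size = NULL,
                  learning_rate = NULL, weight_exponent = 0.5,
                  verbose = FALSE) {
  stopifnot(inherits(model, "broiler_recognizer"), length(dataset) > 0)
  tr <- model$config$training
  if (is.null(epochs)) epochs <- tr$epochs
  if (is.null(batch_size)) batch_size <- tr$batch_size
  if (is.null(learning_rate)) learning_rate <- tr$learning_rate
  lab_all <- unlist(lapply(dataset, `[[`, "labels"))
  stopifnot(all(lab_all %in% MODEL_CLASSES))
  if (length(unique(lab_all)) < 2)
    stop("dataset contains a single class (", unique(lab_all),
         "); at least 2 classes are required for training")
  n_frames <- nrow(dataset[[1]]$spect)
  stopifnot(all(vapply(dataset, function(e) nrow(e$spect), 0) == n_frames))
  t_out <- n_frames %/% 24
  stopifnot(all(vapply(dataset, function(e) length(e$labels), 0) == t_out))

  # tempered inverse-frequency class weights: 1/n^weight_exponent. The
  # exponent 0.5 counters the background-class imbalance while avoiding the
  # confident minority-class false positives on background that full
  # inverse-frequency weighting produces at the 0.7 detection threshold.
  counts <- table(factor(lab_all, levels = MODEL_CLASSES))
  w <- ifelse(counts > 0, 1 / pmax(counts, 1)^weight_exponent, 0)
  w <- w / sum(w[counts > 0]) * sum(counts > 0)
  X <- do.call(cbind, lapply(dataset, function(e)
    matrix(as.vector(t(e$spect)), ncol = 1)))
  X <- (X + model$input_shift) / model$input_scale
  Y <- vapply(dataset, function(e)
    match(e$labels, MODEL_CLASSES) - 1L, integer(t_out))
  Y <- matrix(as.integer(Y), nrow = t_out)
  ages <- vapply(dataset, `[[`, 0, "age_days")

  # step learning-rate decay: final third of the epochs at lr / 5
  lr_ep <- rep(learning_rate, epochs)
  if (epochs >= 6) lr_ep[seq(epochs - epochs %/% 3 + 1, epochs)] <-
    learning_rate / 5
  phases <- if (tr$two_phase) {
    list(list(epochs = tr$phase1_epochs, lr = rep(learning_rate,
                                                  tr$phase1_epochs),
              head_only = TRUE),
         list(epochs = epochs, lr = lr_ep / 5, head_only = FALSE))
  } else list(list(epochs = epochs, lr = lr_ep, head_only = FALSE))

  st <- adam_init(model)
  history <- NULL
  bn_mom <- 0.1
  model <- with_seed(model$config$seed, {
    for (ph in phases) {
      for (ep in seq_len(ph$epochs)) {
        ord <- sample(length(dataset))
        losses <- c(0, 0)
        nb <- 0
        for (b0 in seq(1, length(ord), by = batch_size)) {
          idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
          xb <- matrix(as.vector(X[, idx]), nrow = 1)
          step <- cpp_train_step(model$layers, model$head, xb,
                                 n_frames, 64L, length(idx),
                                 Y[, idx, drop = FALSE], ages[idx],
                                 as.numeric(w), tr$age_loss_weight)
          st$t <- st$t + 1
          # head update
          for (nm in c("W", "b")) {
            up <- adam_update(model$head[[nm]], step$head_grads[[nm]],
                              list(m = st$head$m[[nm]], v = st$head$v[[nm]]),
                              ph$lr[ep], t = st$t)
            model$head[[nm]] <- up$p
            st$head$m[[nm]] <- up$m; st$head$v[[nm]] <- up$v
          }
          for (i in seq_along(model$layers)) {
            # BN running statistics always track the batch statistics
            bs <- step$bn_stats[[i]]
            model$layers[[i]]$rmean <-
              (1 - bn_mom) * model$layers[[i]]$rmean + bn_mom * bs$mean
            model$layers[[i]]$rvar <-
              (1 - bn_mom) * model$layers[[i]]$rvar + bn_mom * bs$var
            if (ph$head_only) next
            for (nm in c("W", "b", "gamma", "beta")) {
              g <- step$grads[[i]][[nm]]
              up <- adam_update(model$layers[[i]][[nm]], g,
                                list(m = st$layers[[i]]$m[[nm]],
                                     v = st$layers[[i]]$v[[nm]]),
                                ph$lr[ep], t = st$t)
              model$layers[[i]][[nm]] <- up$p
              st$layers[[i]]$m[[nm]] <- up$m
              st$layers[[i]]$v[[nm]] <- up$v
            }
          }
          losses <- losses + c(step$loss_class, step$loss_age)
          nb <- nb + 1
        }
        history <- rbind(history,
                         data.frame(phase = ph$head_only + 1,
                                    epoch = ep,
                                    loss_class = losses[1] / nb,
                                    loss_age = losses[2] / nb))
        if (verbose)
          message(sprintf("epoch %d: class %.4f age %.2f", ep,
                          losses[1] / nb, losses[2] / nb))
      }
    }
    model
  })
  model$history <- history
  model$trained <- TRUE
  model
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a recognizer on labeled examples
#'
#' Computes the raster-row confusion matrix, per-class recall, and balanced
#' accuracy (mean per-class recall over classes present in the data) - the
#' metric robust to the heavy background-class imbalance of farm audio.
#'
#' @param model A `broiler_recognizer`.
#' @param dataset As in [train()].
#' @return List with `balanced_accuracy`, `per_class_recall`, `confusion`
#'   (true classes in rows, predictions in columns).
#' @export
evaluate <- function(model, dataset) {
  if (!length(dataset)) stop("empty dataset")
  truth <- character(0); pred <- character(0)
  for (e in dataset) {
    r <- infer(model, e$spect)
    k <- min(nrow(r$scores), length(e$labels))
    pred <- c(pred, MODEL_CLASSES[max.col(r$scores[seq_len(k), ,
                                                   drop = FALSE])])
    truth <- c(truth, e$labels[seq_len(k)])
  }
  confusion_metrics(truth, pred)
}

# Shared by evaluate() and raster-level checks.
confusion_metrics <- function(truth, pred) {
  cm <- table(factor(truth, levels = MODEL_CLASSES),
              factor(pred, levels = MODEL_CLASSES))
  support <- rowSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, NA)
  names(recall) <- MODEL_CLASSES
  list(balanced_accuracy = mean(recall, na.rm = TRUE),
       per_class_recall = recall, confusion = cm)
}

# ---- persistence ------------------------------------------------------------

#' Save / load a recognizer checkpoint
#'
#' One file holding all parameters, running statistics and the embedded
#' config.
#'
#' @param model A `broiler_recognizer`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "broiler_recognizer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "broiler_recognizer"))
  m
}
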