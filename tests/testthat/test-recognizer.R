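# Recognizer: architecture contracts, inference invariants, training.

test_that("parameter count sits in the contracted band and is enforced", {
  m <- build_model()
  expect_gte(n_parameters(m), 0.96e6)
  expect_lte(n_parameters(m), 1.44e6)
  expect_equal(n_parameters(m),
               broilervoc:::count_parameters_config(m$config))
  # an oversized configuration is rejected with the actual count
  big <- recognizer_config(channels = c(16, 16, 32, 32, 64, 64, 256,
                                        256, 256, 384, 384))
  expect_error(build_model(big), "[0-9]{7}")
  small <- recognizer_config(channels = c(8, 8, 16, 16, 32, 32, 64,
                                          64, 64, 96, 96))
  expect_error(build_model(small), "outside tolerance")
})

test_that("output length follows the floor(frames / 24) rule", {
  m <- build_model()
  set.seed(1)
  for (frames in c(6000, 6024, 6010, 240, 24, 47)) {
    r <- infer(m, matrix(rnorm(frames * 64), frames, 64))
    expect_equal(nrow(r$scores), frames %/% 24)
  }
  # shorter than one prediction step: empty raster
  r0 <- infer(m, matrix(rnorm(23 * 64), 23, 64))
  expect_equal(nrow(r0$scores), 0)
  expect_length(r0$age_estimate, 0)
})

test_that("every raster row is a probability distribution", {
  m <- build_model()
  set.seed(2)
  for (i in 1:20) {
    sp <- matrix(rnorm(96 * 64, sd = runif(1, 0.5, 3)), 96, 64)
    r <- infer(m, sp)
    expect_lt(max(abs(rowSums(r$scores) - 1)), 1e-5)
    expect_true(all(r$scores >= 0 & r$scores <= 1))
    expect_true(all(r$age_estimate >= 0))
  }
})

test_that("inference is shift-equivariant by one stride step", {
  m <- build_model()
  set.seed(3)
  x <- matrix(rnorm(480 * 64), 480, 64)
  r_full <- infer(m, x)$scores
  r_cut <- infer(m, x[-(1:24), , drop = FALSE])$scores
  # away from receptive-field edges, row k+1 of the full input equals
  # row k of the 24-frame-delayed input
  edge <- 6
  keep <- (edge + 1):(nrow(r_cut) - edge)
  expect_equal(r_full[keep + 1, ], r_cut[keep, ], tolerance = 1e-8)
})

test_that("concatenated segments reproduce per-segment rasters interiorly", {
  m <- build_model()
  set.seed(4)
  a <- matrix(rnorm(240 * 64), 240, 64)
  b <- matrix(rnorm(240 * 64), 240, 64)
  rab <- infer(m, rbind(a, b))$scores
  ra <- infer(m, a)$scores
  rb <- infer(m, b)$scores
  edge <- 6
  expect_equal(rab[1:(10 - edge), ], ra[1:(10 - edge), ],
               tolerance = 1e-8)
  expect_equal(rab[(10 + edge + 1):20, ], rb[(edge + 1):10, ],
               tolerance = 1e-8)
})

test_that("training refuses single-class data and is seed-deterministic", {
  ds1 <- make_training_set(n_per_class = 4, classes = "background",
                           snippet_s = 0.96, seed = 1)
  m <- build_model(recognizer_config(seed = 7))
  expect_error(train(m, ds1), "single class")
  ds <- make_training_set(n_per_class = 6,
                          classes = c("background", "DC"),
                          snippet_s = 0.96, seed = 2)
  t1 <- train(m, ds, epochs = 1)
  t2 <- train(m, ds, epochs = 1)
  expect_identical(t1$history$loss_class, t2$history$loss_class)
  expect_identical(t1$layers[[11]]$W, t2$layers[[11]]$W)
})

test_that("loss history trends downward over training", {
  tm <- get_tiny_trained()
  h <- tm$model$history$loss_class
  expect_lt(mean(tail(h, 2)), mean(head(h, 2)))
})

test_that("a two-class toy model separates call from background", {
  tm <- get_tiny_trained()
  ev <- evaluate(tm$model, tm$holdout)
  expect_gt(ev$balanced_accuracy, 0.9)
  # pure background spectrograms are modally background
  set.seed(6)
  bg <- make_training_set(n_per_class = 6, classes = "background",
                          snippet_s = 1.2, seed = 41)
  sc <- do.call(rbind, lapply(bg, function(e)
    infer(tm$model, e$spect)$scores))
  expect_gt(mean(max.col(sc) == 1), 0.9)
})

test_that("evaluation metrics match their definitions", {
  cm <- broilervoc:::confusion_metrics(
    truth = c("DC", "DC", "SP", "background"),
    pred = c("DC", "DC", "SP", "background"))
  expect_equal(cm$balanced_accuracy, 1.0)
  expect_equal(sum(cm$confusion), 4)
  # row sums equal per-class support
  set.seed(9)
  truth <- sample(MODEL_CLASSES, 600, replace = TRUE)
  pred <- sample(MODEL_CLASSES, 600, replace = TRUE)
  cm2 <- broilervoc:::confusion_metrics(truth, pred)
  expect_equal(as.numeric(rowSums(cm2$confusion)),
               as.numeric(table(factor(truth, MODEL_CLASSES))))
  # uniform-random predictions sit near chance = 1/6
  expect_lt(abs(cm2$balanced_accuracy - 1 / 6), 0.06)
  expect_error(evaluate(build_model(), list()), "empty")
})

test_that("checkpoints round-trip through a single file", {
  tm <- get_tiny_trained()
  f <- tempfile(fileext = ".ckpt")
  save_model(tm$model, f)
  m2 <- load_model(f)
  expect_identical(m2$layers, tm$model$layers)
  expect_identical(m2$config, tm$model$config)
  set.seed(10)
  sp <- matrix(rnorm(96 * 64), 96, 64)
  expect_identical(infer(m2, sp)$scores, infer(tm$model, sp)$scores)
})

test_that("the age head is auxiliary: disabling it keeps class accuracy", {
  accs <- sapply(c(0, 0.1), function(aw) {
    sapply(1:2, function(s) {
      ds <- make_training_set(n_per_class = 10,
                              classes = c("background", "DC"),
                              snippet_s = 0.96, seed = 50 + s)
      cfgm <- recognizer_config(seed = s, epochs = 3,
                                age_loss_weight = aw)
      m <- train(build_model(cfgm), ds)
      ho <- make_training_set(n_per_class = 6,
                              classes = c("background", "DC"),
                              snippet_s = 0.96, seed = 90 + s)
      evaluate(m, ho)$balanced_accuracy
    })
  })
  expect_lt(abs(mean(accs[, 1]) - mean(accs[, 2])), 0.2)
})
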