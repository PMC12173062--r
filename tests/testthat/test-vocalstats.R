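# Statistical stage: Tukey HSD, letters, mixed model, THI.

test_that("tukey_hsd reproduces the stats::TukeyHSD oracle", {
  set.seed(1)
  g <- rep(c("a", "b", "c", "d"), times = c(8, 10, 9, 12))
  y <- rnorm(length(g)) + rep(c(0, 0.5, 1.5, 0.2), times = c(8, 10, 9, 12))
  ours <- tukey_hsd(y, g)
  ref <- stats::TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  # same pair ordering: b-a, c-a, d-a, c-b, d-b, d-c
  key <- paste0(ours$pairs$group2, "-", ours$pairs$group1)
  expect_equal(ours$pairs$diff, unname(ref[key, "diff"]),
               tolerance = 1e-10)
  expect_equal(ours$pairs$p, unname(ref[key, "p adj"]), tolerance = 1e-8)
})

test_that("two-group Tukey equals the equal-variance t-test", {
  set.seed(2)
  y <- c(rnorm(12), rnorm(15) + 0.8)
  g <- rep(c("x", "z"), c(12, 15))
  p_tukey <- tukey_hsd(y, g)$pairs$p
  p_t <- t.test(y ~ g, var.equal = TRUE)$p.value
  expect_equal(p_tukey, p_t, tolerance = 1e-10)
})

test_that("degenerate groupings produce the expected letters", {
  y <- rep(5, 12)
  g <- rep(c("a", "b", "c"), 4)
  res <- tukey_hsd(y, g)
  expect_true(all(res$pairs$p == 1))
  expect_true(all(res$letters == "a"))
  # three well-separated groups get three distinct letters
  set.seed(3)
  y2 <- c(rnorm(20), rnorm(20) + 10, rnorm(20) + 20)
  g2 <- rep(c("lo", "mid", "hi"), each = 20)
  l2 <- tukey_hsd(y2, g2)$letters
  expect_equal(sort(unname(l2)), c("a", "b", "c"))
  expect_equal(unname(l2["hi"]), "a")  # ordered by decreasing mean
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("letter displays are reconstructible from the p-value matrix", {
  set.seed(4)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    means <- rnorm(k, sd = sample(c(0.2, 1, 4), 1))
    y <- rnorm(k * 8, mean = rep(means, each = 8))
    g <- rep(letters[1:k], each = 8)
    res <- tukey_hsd(y, g)
    share <- function(i, j) {
      any(strsplit(res$letters[i], "")[[1]] %in%
            strsplit(res$letters[j], "")[[1]])
    }
    for (r in seq_len(nrow(res$pairs))) {
      i <- res$pairs$group1[r]; j <- res$pairs$group2[r]
      if (res$pairs$p[r] < 0.05) expect_false(share(i, j))
      else expect_true(share(i, j))
    }
    expect_true(all(nchar(res$letters) >= 1))
  }
})

test_that("THI is monotone in temperature and matches the frozen value", {
  expect_true(all(diff(compute_thi(seq(10, 40, 2), 50)) > 0))
  for (f in c("poultry_wb", "thom", "nrc"))
    expect_true(all(diff(compute_thi(seq(10, 40, 2), 70, f)) > 0))
  # hand-computed spot value of the default formula at 30 C, 50% RH:
  # wet bulb (Stull) = 22.294 C; 0.85*30 + 0.15*22.294 = 28.84
  expect_equal(compute_thi(30, 50), 28.844, tolerance = 1e-3)
  expect_error(compute_thi(60, 50), "range")
  expect_error(compute_thi(25, 120), "rh")
})

test_that("THI ANOVA finds separation, stays calibrated, flags aliasing", {
  # strong treatment separation
  set.seed(5)
  rec <- expand.grid(treatment = c("HS", "TN"), round = 1:3,
                     time = c("10:00", "12:00", "14:00"), rep = 1:4)
  rec$thi <- ifelse(rec$treatment == "HS", 26, 19) + rnorm(nrow(rec), 0, 1)
  rep1 <- anova_thi(rec)
  expect_lt(rep1$anova$p[rep1$anova$term == "treatment"], 0.001)
  expect_true("treatment" %in% names(rep1$posthoc))
  # permutation calibration of the treatment test under the null
  set.seed(6)
  base <- rec
  pvals <- replicate(200, {
    # permute treatment within each round x time stratum so the factorial
    # design stays full rank
    for (r in unique(base$round)) for (tm in unique(base$time)) {
      i <- base$round == r & base$time == tm
      base$treatment[i] <- sample(base$treatment[i])
    }
    base$thi <- 20 + rnorm(nrow(base))
    a <- anova_thi(base)
    a$anova$p[a$anova$term == "treatment"]
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.11)
  # all-equal data: nothing significant
  rec0 <- rec
  rec0$thi <- 21
  a0 <- anova_thi(rec0)
  expect_false(any(a0$anova$p < 0.05, na.rm = TRUE))
  # aliased design is rejected with the offending terms named
  reca <- rec
  reca$round <- ifelse(reca$treatment == "HS", 1, 2)
  expect_error(anova_thi(reca), "aliased")
})

test_that("temperature derivation inside anova_thi uses the registry", {
  rec <- expand.grid(treatment = c("HS", "TN"), round = 1:2,
                     time = c("10:00", "12:00"), rep = 1:3)
  set.seed(7)
  rec$temp_c <- ifelse(rec$treatment == "HS", 30, 21) + rnorm(nrow(rec))
  rec$rh <- 55
  a <- anova_thi(rec)
  expect_lt(a$anova$p[a$anova$term == "treatment"], 0.01)
})

test_that("fit_duration_model detects a planted evening effect", {
  tab <- simulate_observation_table(bin_effects = c(0, 0, 0, 3),
                                    sd_resid = 1, seed = 11)
  rep1 <- fit_duration_model(tab)
  expect_lt(rep1$anova$p[rep1$anova$term == "bin"], 0.001)
  lets <- rep1$posthoc$bin$letters
  expect_false(any(strsplit(lets["evening"], "")[[1]] %in%
                     unlist(strsplit(lets[names(lets) != "evening"], ""))))
})

test_that("constant observations yield no effects and shared letters", {
  tab <- simulate_observation_table(sd_pen = 0, sd_compartment = 0,
                                    sd_resid = 0, seed = 1)
  suppressWarnings(
    expect_warning(rep0 <- fit_duration_model(tab), "falling back"))
  expect_false(any(rep0$anova$p < 0.05, na.rm = TRUE))
  expect_length(rep0$posthoc, 0)
})

test_that("interaction pruning removes a null interaction", {
  tab <- simulate_observation_table(bin_effects = c(0, 1, 2, 1),
                                    enrichment_effect = 0.5, seed = 21)
  rep1 <- fit_duration_model(tab)
  expect_false(rep1$interaction_retained)
  an_terms <- rep1$anova$term
  expect_false(any(grepl(":", an_terms)))
  # with pruning disabled the interaction stays in the model
  rep2 <- fit_duration_model(tab, prune_interaction = FALSE)
  expect_true(any(grepl(":", rep2$anova$term)))
})

test_that("single-level factors and missing columns are rejected", {
  tab <- simulate_observation_table(seed = 2)
  tab$enrichment <- "MP"
  expect_error(fit_duration_model(tab), "fewer than 2 levels")
  tab2 <- simulate_observation_table(seed = 2)
  tab2$bin <- NULL
  expect_error(fit_duration_model(tab2), "bin")
})

test_that("a long table is filtered to the requested sound type", {
  tab <- rbind(
    cbind(simulate_observation_table(seed = 3), type = "DC"),
    cbind(simulate_observation_table(bin_effects = c(0, 0, 0, 5),
                                     seed = 4), type = "SP"))
  rep_dc <- fit_duration_model(tab, sound_type = "DC", posthoc = FALSE)
  rep_sp <- fit_duration_model(tab, sound_type = "SP", posthoc = FALSE)
  expect_gt(rep_dc$anova$p[rep_dc$anova$term == "bin"], 0.01)
  expect_lt(rep_sp$anova$p[rep_sp$anova$term == "bin"], 0.001)
})
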