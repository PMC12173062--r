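#' @title Statistical analysis of vocalization durations
#' @description The inferential stage: least-squares regression of binned
#'   durations on treatment and time of day with pen and compartment as
#'   random effects, non-significant interaction pruning, Tukey HSD
#'   post-hoc comparisons with compact letter displays, and the
#'   temperature-humidity index (THI) with its three-factor ANOVA.
#' @name vocalstats
NULL

# ---- Tukey HSD --------------------------------------------------------------

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' One-way Tukey-Kramer honestly-significant-difference test based on the
#' studentized range distribution, plus a compact letter display in which
#' groups that are not significantly different share a letter.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor); every group needs
#'   `n >= 2`.
#' @param alpha Significance level for the letters (default 0.05).
#' @return List with `means` (named group means), `pairs` (data frame of
#'   pairwise differences and adjusted p-values), and `letters` (named
#'   character vector).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  means <- tapply(values, groups, mean)
  N <- length(values)
  df <- N - k
  mse <- sum(tapply(values, groups, function(x)
    sum((x - mean(x))^2))) / df
  cmb <- utils::combn(levels(groups), 2)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ])
  pairs$diff <- as.numeric(means[pairs$group2] - means[pairs$group1])
  se <- as.numeric(sqrt(mse / 2 * (1 / n[pairs$group1] +
                                     1 / n[pairs$group2])))
  q <- abs(pairs$diff) / se
  pairs$p <- if (mse == 0) ifelse(abs(pairs$diff) > 0, 0, 1)
  else as.numeric(ptukey(q, k, df, lower.tail = FALSE))
  rownames(pairs) <- NULL
  letters <- cld_letters(levels(groups), pairs, alpha, order_by = -means)
  list(means = means, pairs = pairs, letters = letters, df = df,
       mse = mse)
}

# Compact letter display by insert-and-absorb: start from one group
# containing all levels; for each significant pair, split every letter
# group containing both; drop groups that are subsets of others. Letters
# are assigned in order of decreasing mean (largest mean gets "a").
cld_letters <- function(levels, pairs, alpha = 0.05, order_by = NULL) {
  k <- length(levels)
  cols <- list(rep(TRUE, k))
  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group1[r], levels)
    j <- match(sig$group2[r], levels)
    newcols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        newcols <- c(newcols, list(a, b))
      } else newcols <- c(newcols, list(col))
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(newcols))
    for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
      if (u != v && keep[u] && keep[v] &&
          all(newcols[[u]] <= newcols[[v]]) &&
          !identical(newcols[[u]], newcols[[v]]))
        keep[u] <- FALSE
    }
    # drop exact duplicates
    cols <- unique(newcols[keep])
  }
  ord <- if (is.null(order_by)) seq_len(k) else order(order_by)
  rank_of <- integer(k)
  rank_of[ord] <- seq_len(k)
  cols <- cols[order(vapply(cols, function(cc) min(rank_of[cc]), 0))]
  lets <- rep("", k)
  for (ci in seq_along(cols))
    lets[cols[[ci]]] <- paste0(lets[cols[[ci]]], letters[ci])
  names(lets) <- levels
  lets
}

# ---- duration mixed model ---------------------------------------------------

#' Fit the treatment x time-of-day model for one sound type
#'
#' Least-squares linear regression of mean s/min on the treatment factors
#' and the diurnal time bin, with random intercepts for pen (the
#' experimental unit) and compartment, fitted by REML with
#' Satterthwaite denominator degrees of freedom. Interactions between time
#' bin and each treatment are removed from the final model when not
#' significant (p >= alpha). Factors that are constant within pens (the
#' treatments, in the trial design) are tested against between-pen
#' variation with the classical balanced split-plot F on pen means -
#' exact under normality, where Satterthwaite approximations become
#' anti-conservative when the pen variance estimate collapses to the
#' boundary. Significant factors get Tukey-corrected
#' pairwise comparisons and compact letter displays. Residual normality is
#' checked and reported as a diagnostic, not enforced; observations with
#' |studentized residual| > 3 are flagged, never removed.
#'
#' @param table Observation data frame: response column (default
#'   `mean_s_per_min`), factor columns for `bin` and each treatment, and
#'   the random-effect id columns. If a `type` column is present it is
#'   filtered to `sound_type`.
#' @param sound_type Optional call type to select from a long table.
#' @param treatments Character vector of treatment column names (e.g.
#'   `"enrichment"`, `"temperature"`); each needs >= 2 levels.
#' @param response Response column name.
#' @param random Random-intercept id columns present in `table`
#'   (microphone nesting is implicit when one row per microphone is
#'   supplied; set `random = c("pen", "compartment", "microphone")` to add
#'   a third level).
#' @param alpha Significance level.
#' @param prune_interaction Remove non-significant treatment x bin
#'   interactions and refit.
#' @param posthoc Compute Tukey pairwise comparisons and letters for
#'   significant factors.
#' @return Object of class `effects_report`: list with `anova` (omnibus
#'   table), `interaction_retained`, `posthoc` (per significant factor:
#'   estimated marginal means, Tukey-adjusted pairs, letters),
#'   `diagnostics`, and the fitted `model`.
#' @export
fit_duration_model <- function(table, sound_type = NULL,
                               treatments = "enrichment",
                               response = "mean_s_per_min",
                               random = c("pen", "compartment"),
                               alpha = 0.05, prune_interaction = TRUE,
                               posthoc = TRUE) {
  if (!is.null(sound_type) && "type" %in% names(table))
    table <- table[table$type == sound_type, , drop = FALSE]
  stopifnot(nrow(table) > 0, response %in% names(table),
            "bin" %in% names(table))
  for (f in c("bin", treatments, random)) {
    if (!f %in% names(table)) stop("missing column: ", f)
    table[[f]] <- factor(table[[f]])
  }
  for (f in c("bin", treatments)) {
    if (nlevels(droplevels(table[[f]])) < 2)
      stop("factor '", f, "' has fewer than 2 levels")
  }
  fixed <- paste(c("bin", treatments,
                   paste0("bin:", treatments)), collapse = " + ")
  ranef_str <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  fit_once <- function(fixed_str) {
    fml <- stats::as.formula(paste(response, "~", fixed_str, "+",
                                   ranef_str))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = table, REML = TRUE))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("mixed-model fit failed (", conditionMessage(fit),
              "); falling back to fixed-effects-only least squares")
      fml2 <- stats::as.formula(paste(response, "~", fixed_str))
      return(lm(fml2, data = table))
    }
    fit
  }
  omnibus <- function(fit) {
    if (inherits(fit, "lmerModLmerTest")) {
      a <- suppressMessages(anova(fit, type = 3))
      data.frame(term = rownames(a), F = a$`F value`,
                 p = a$`Pr(>F)`, row.names = NULL)
    } else {
      a <- anova(fit)
      a <- a[rownames(a) != "Residuals", , drop = FALSE]
      data.frame(term = rownames(a), F = a$`F value`,
                 p = a$`Pr(>F)`, row.names = NULL)
    }
  }
  # Exact whole-plot tests: a factor constant within pens (the
  # experimental unit) is tested against between-pen variation using the
  # classical balanced split-plot F on pen means, with any coarser
  # grouping (compartment) as a fixed block. Satterthwaite approximations
  # are anti-conservative for such factors when the pen variance estimate
  # collapses to the boundary; the whole-plot F is exact under normality
  # for balanced designs.
  whole_plot_p <- function() {
    if (!"pen" %in% random) return(NULL)
    pen_rows <- split(seq_len(nrow(table)), table$pen)
    balanced <- length(unique(lengths(pen_rows))) == 1
    constant_in_pen <- function(f) all(vapply(pen_rows, function(i)
      length(unique(table[[f]][i])) == 1, TRUE))
    wp <- treatments[vapply(treatments, constant_in_pen, TRUE)]
    if (!balanced || !length(wp)) return(NULL)
    blocks <- setdiff(random[vapply(random, constant_in_pen, TRUE)], "pen")
    agg_fml <- stats::as.formula(paste(
      response, "~", paste(c("pen", blocks, wp), collapse = " + ")))
    pm <- stats::aggregate(agg_fml, table, mean)
    resid_df <- nrow(pm) - 1 -
      sum(vapply(c(blocks, wp), function(f)
        nlevels(droplevels(factor(pm[[f]]))) - 1, 0))
    if (resid_df < 1) return(NULL)
    fitp <- lm(stats::as.formula(paste(
      response, "~", paste(c(blocks, wp), collapse = " + "))), pm)
    out <- lapply(wp, function(f) {
      d1 <- stats::drop1(fitp, stats::as.formula(paste("~", f)),
                         test = "F")
      list(F = d1[f, "F value"], p = d1[f, "Pr(>F)"])
    })
    names(out) <- wp
    out
  }
  wp_tests <- whole_plot_p()
  apply_wp <- function(an) {
    for (f in names(wp_tests)) {
      i <- an$term == f
      an$F[i] <- wp_tests[[f]]$F
      an$p[i] <- wp_tests[[f]]$p
    }
    an
  }
  fit <- fit_once(fixed)
  an <- apply_wp(omnibus(fit))
  inter_terms <- grep(":", an$term, value = TRUE)
  interaction_retained <- TRUE
  if (prune_interaction && length(inter_terms)) {
    inter_p <- an$p[an$term %in% inter_terms]
    if (all(is.na(inter_p)) || all(inter_p >= alpha, na.rm = TRUE)) {
      fixed <- paste(c("bin", treatments), collapse = " + ")
      fit <- fit_once(fixed)
      an <- apply_wp(omnibus(fit))
      interaction_retained <- FALSE
    }
  }
  ph <- list()
  if (posthoc) {
    for (f in c("bin", treatments)) {
      p_f <- an$p[an$term == f]
      if (!length(p_f) || is.na(p_f) || p_f >= alpha) next
      em <- suppressMessages(emmeans::emmeans(
        fit, stats::as.formula(paste0("~", f)),
        lmer.df = "satterthwaite"))
      prs <- as.data.frame(emmeans::contrast(em, "pairwise",
                                             adjust = "tukey"))
      emd <- as.data.frame(em)
      lv <- as.character(emd[[f]])
      sides <- do.call(rbind, strsplit(prs$contrast, " - "))
      pair_df <- data.frame(group1 = trimws(sides[, 1]),
                            group2 = trimws(sides[, 2]),
                            diff = -prs$estimate, p = prs$p.value)
      # emmeans wraps non-syntactic level names in parentheses
      pair_df$group1 <- gsub("^\\(|\\)$", "", pair_df$group1)
      pair_df$group2 <- gsub("^\\(|\\)$", "", pair_df$group2)
      lets <- cld_letters(lv, pair_df, alpha,
                          order_by = -emd$emmean)
      ph[[f]] <- list(emmeans = emd, pairs = pair_df, letters = lets)
    }
  }
  res <- resid(fit)
  rs <- tryCatch(rstudent(fit), error = function(e) res / sd(res))
  diag <- list(
    outliers = which(abs(rs) > 3),
    shapiro_p = if (length(res) >= 3 && length(res) <= 5000 &&
                    sd(res) > 0) shapiro.test(res)$p.value else NA,
    singular = inherits(fit, "merMod") && lme4::isSingular(fit))
  structure(list(anova = an, interaction_retained = interaction_retained,
                 posthoc = ph, diagnostics = diag, model = fit,
                 alpha = alpha),
            class = "effects_report")
}

#' @export
print.effects_report <- function(x, ...) {
  cat("Effects report (alpha =", x$alpha, ")\n\nOmnibus tests:\n")
  print(transform(x$anova, F = round(F, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat("\nInteraction retained:", x$interaction_retained, "\n")
  for (f in names(x$posthoc)) {
    ph <- x$posthoc[[f]]
    cat("\nTukey HSD groups for", f, ":\n")
    lv <- as.character(ph$emmeans[[f]])
    tab <- data.frame(level = lv,
                      mean = round(ph$emmeans$emmean, 3),
                      SEM = round(ph$emmeans$SE, 3),
                      letters = ph$letters[lv])
    print(tab, row.names = FALSE)
  }
  if (x$diagnostics$singular)
    cat("\nNote: singular random-effect fit\n")
  invisible(x)
}

# ---- THI --------------------------------------------------------------------

#' Temperature-humidity index
#'
#' Computes THI from dry-bulb temperature and relative humidity. The exact
#' index formula used for the original climate records is not public, so a
#' registry of standard formulas is provided and the choice is explicit:
#' \describe{
#'   \item{`poultry_wb`}{(default, a documented stand-in)
#'     `0.85 * T_db + 0.15 * T_wb`, with wet-bulb temperature from the
#'     Stull (2011) psychrometric approximation.}
#'   \item{`thom`}{`T - 0.55 * (1 - RH/100) * (T - 14.5)`.}
#'   \item{`nrc`}{Fahrenheit-based `(1.8T + 32) - (0.55 - 0.0055 RH)
#'     (1.8T - 26)`.}
#' }
#' All are monotone increasing in temperature at fixed humidity.
#'
#' @param temp_c Dry-bulb temperature, degrees C, in (-10, 50).
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @param formula Registry key.
#' @return THI values (same units/scale as the chosen formula).
#' @export
compute_thi <- function(temp_c, rh,
                        formula = c("poultry_wb", "thom", "nrc")) {
  formula <- match.arg(formula)
  if (any(!is.finite(temp_c)) || any(temp_c <= -10) || any(temp_c >= 50))
    stop("temp_c out of plausible range (-10, 50)")
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100))
    stop("rh must be in [0, 100]")
  switch(formula,
    poultry_wb = {
      tw <- wet_bulb_stull(temp_c, rh)
      0.85 * temp_c + 0.15 * tw
    },
    thom = temp_c - 0.55 * (1 - rh / 100) * (temp_c - 14.5),
    nrc = (1.8 * temp_c + 32) -
      (0.55 - 0.0055 * rh) * (1.8 * temp_c - 26))
}

# Stull (2011) wet-bulb approximation, valid for ordinary barn climates.
wet_bulb_stull <- function(t, rh) {
  t * atan(0.151977 * sqrt(rh + 8.313659)) + atan(t + rh) -
    atan(rh - 1.676331) + 0.00391838 * rh^1.5 * atan(0.023101 * rh) -
    4.686035
}

#' Three-factor ANOVA of THI records
#'
#' ANOVA of THI on treatment (HS vs TN), round (1-3) and time of day, with
#' all interactions, followed by Tukey HSD on significant main factors.
#'
#' @param records Data frame with columns `thi` (or `temp_c` + `rh`, from
#'   which THI is computed), `treatment`, `round`, `time`.
#' @param formula THI formula key, see [compute_thi()].
#' @param alpha Significance level.
#' @return Object of class `effects_report`.
#' @export
anova_thi <- function(records, formula = "poultry_wb", alpha = 0.05) {
  if (!"thi" %in% names(records)) {
    stopifnot(all(c("temp_c", "rh") %in% names(records)))
    records$thi <- compute_thi(records$temp_c, records$rh, formula)
  }
  for (f in c("treatment", "round", "time"))
    records[[f]] <- factor(records[[f]])
  mm <- model.matrix(~ treatment * round * time, records)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  fit <- aov(thi ~ treatment * round * time, data = records)
  a <- summary(fit)[[1]]
  a <- a[rownames(a) != "Residuals", , drop = FALSE]
  an <- data.frame(term = trimws(rownames(a)), F = a$`F value`,
                   p = a$`Pr(>F)`, row.names = NULL)
  ph <- list()
  for (f in c("treatment", "round", "time")) {
    p_f <- an$p[an$term == f]
    if (length(p_f) && !is.na(p_f) && p_f < alpha)
      ph[[f]] <- tukey_hsd(records$thi, records[[f]], alpha)
  }
  structure(list(anova = an, interaction_retained = TRUE, posthoc = ph,
                 diagnostics = list(singular = FALSE), model = fit,
                 alpha = alpha),
            class = "effects_report")
}

# ---- simulation of observation tables ---------------------------------------

#' Simulate an observation table for calibration studies
#'
#' Emulates the trial design: compartments with pens nested inside, two
#' microphones per pen, enrichment assigned to one pen per compartment,
#' and one aggregated observation per microphone x diurnal bin. The
#' response is Gaussian: grand mean + bin effect + enrichment effect +
#' pen and compartment random intercepts + residual.
#'
#' @param n_compartments,pens_per_compartment,mics_per_pen Design sizes.
#' @param mean Grand mean, s/min.
#' @param bin_effects Named or positional numeric vector of effects for
#'   night/morning/midday/evening.
#' @param enrichment_effect Additive effect of the enriched (MP) pens.
#' @param sd_pen,sd_compartment,sd_resid Standard deviations of the pen
#'   and compartment random intercepts and the residual.
#' @param seed RNG seed.
#' @return Data frame with columns `pen, compartment, microphone,
#'   enrichment, bin, mean_s_per_min`.
#' @export
simulate_observation_table <- function(n_compartments = 4,
                                       pens_per_compartment = 2,
                                       mics_per_pen = 2, mean = 5,
                                       bin_effects = c(0, 0, 0, 0),
                                       enrichment_effect = 0,
                                       sd_pen = 0.5, sd_compartment = 0.3,
                                       sd_resid = 1, seed = 1L) {
  bins <- c("night", "morning", "midday", "evening")
  with_seed(seed, {
    rows <- expand.grid(bin = bins, microphone = seq_len(mics_per_pen),
                        pen_in = seq_len(pens_per_compartment),
                        compartment = seq_len(n_compartments),
                        KEEP.OUT.ATTRS = FALSE)
    rows$pen <- paste0("c", rows$compartment, "p", rows$pen_in)
    rows$compartment <- paste0("c", rows$compartment)
    rows$microphone <- paste0(rows$pen, "m", rows$microphone)
    rows$enrichment <- ifelse(rows$pen_in == 1, "MP", "NMP")
    pen_re <- setNames(rnorm(length(unique(rows$pen)), 0, sd_pen),
                       unique(rows$pen))
    comp_re <- setNames(rnorm(length(unique(rows$compartment)), 0,
                              sd_compartment), unique(rows$compartment))
    be <- setNames(rep(bin_effects, length.out = 4), bins)
    rows$mean_s_per_min <- mean + be[rows$bin] +
      ifelse(rows$enrichment == "MP", enrichment_effect, 0) +
      pen_re[rows$pen] + comp_re[rows$compartment] +
      rnorm(nrow(rows), 0, sd_resid)
    rows$bin <- factor(rows$bin, levels = bins)
    rows[, c("pen", "compartment", "microphone", "enrichment", "bin",
             "mean_s_per_min")]
  })
}

#' Diurnal pattern plot with spline smoothing
#'
#' Visualization utility only (no inferential claims): hourly mean s/min
#' per call type with a periodic smoothing spline overlay.
#'
#' @param hourly Output of [aggregate_hourly()].
#' @param types Call types to draw.
#' @return Invisibly, `NULL`. Draws on the current graphics device.
#' @export
plot_diurnal <- function(hourly, types = CALL_TYPES) {
  stopifnot(all(types %in% names(hourly)))
  ylim <- c(0, max(unlist(hourly[types]), na.rm = TRUE))
  plot(NULL, xlim = c(0, 23), ylim = ylim, xlab = "clock hour",
       ylab = "s/min", main = "Diurnal vocalization pattern")
  cols <- seq_along(types) + 1
  for (i in seq_along(types)) {
    y <- hourly[[types[i]]]
    points(hourly$clock_hour, y, col = cols[i], pch = 16)
    if (length(unique(hourly$clock_hour)) >= 8) {
      sp <- stats::smooth.spline(hourly$clock_hour, y, df = 6)
      lines(predict(sp, seq(0, 23, 0.25)), col = cols[i])
    }
  }
  legend("topright", legend = types, col = cols, pch = 16, bty = "n")
  invisible(NULL)
}
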