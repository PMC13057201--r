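# Seed-deterministic permutation tests, exact binomial and chi-square
# wrappers, and a thin contract to a standard mixed-model routine.

new_perm_test <- function(observed, null, n_shuffles, seed, statistic,
                          two_sided = TRUE, extra = list()) {
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_shuffles)
  structure(c(list(observed_stat = observed,
                   null_mean = mean(null), null_p95 = quantile(null, 0.95, names = FALSE),
                   null_distribution = null,
                   p_value = p, n_shuffles = n_shuffles, seed = seed,
                   statistic = statistic, two_sided = two_sided), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s = %.4g, p = %.4g (%d shuffles, seed %d)\n",
              x$statistic, x$observed_stat, x$p_value, x$n_shuffles, x$seed))
  invisible(x)
}

#' Permutation test for a two-group difference
#'
#' Shuffles group labels wholesale `n_shuffles` times and compares the
#' observed difference of group means (or medians) with the null
#' distribution. The two-sided p-value uses the add-one estimator
#' `(1 + #{|stat*| >= |stat|}) / (1 + n_shuffles)`, so p is never exactly
#' zero and is floored at `1 / (n_shuffles + 1)`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the values and the
#'   two-level group labels.
#' @param statistic `"mean"` (difference of means, default) or `"median"`.
#' @param n_shuffles Number of label shuffles (default 10000).
#' @param seed Integer seed.
#' @return An object of class `perm_test`; see [tidy.perm_test()].
#' @export
permutation_test_groups <- function(data, value, group, statistic = c("mean", "median"),
                                    n_shuffles = 10000L, seed = 1L) {
  statistic <- match.arg(statistic)
  v <- eval_tidy(enquo(value), data)
  g <- as.factor(eval_tidy(enquo(group), data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
  if (min(table(g)) < 2L) abort("each group needs at least two values.")
  fun <- if (statistic == "mean") mean else median
  stat <- function(gg) fun(v[gg == levels(g)[1L]]) - fun(v[gg == levels(g)[2L]])
  obs <- stat(g)
  null <- with_seed(seed, vapply(seq_len(n_shuffles),
                                 function(b) stat(sample(g)), numeric(1)))
  new_perm_test(obs, null, n_shuffles, seed,
                statistic = paste0("diff_of_", statistic, "s"),
                extra = list(groups = levels(g), n = as.vector(table(g))))
}

#' Permutation test for a Pearson correlation
#'
#' Observed Pearson r between `x` and `y`; the null is built by shuffling
#' `y` against `x`. Two-sided add-one p-value as in
#' [permutation_test_groups()].
#'
#' @param data A data frame.
#' @param x,y Numeric columns (tidy-eval).
#' @inheritParams permutation_test_groups
#' @return A `perm_test` object with the Pearson r as observed statistic.
#' @export
permutation_correlation <- function(data, x, y, n_shuffles = 10000L, seed = 1L) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L) abort("need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in `x` or `y`.")
  obs <- cor(xv, yv)
  null <- with_seed(seed, vapply(seq_len(n_shuffles),
                                 function(b) cor(xv, sample(yv)), numeric(1)))
  new_perm_test(obs, null, n_shuffles, seed, statistic = "pearson_r",
                extra = list(n = length(xv)))
}

#' Exact binomial test for a fraction
#'
#' Two-sided exact binomial test of `k` successes in `n` trials against a
#' null proportion `p0`; used e.g. to test whether the responsive-spine
#' fraction differs from one half.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null proportion (default 0.5).
#' @return One-row tibble: `k`, `n`, `estimate`, `p0`, `p_value`.
#' @export
binomial_fraction_test <- function(k, n, p0 = 0.5) {
  check_number(k, "k", lower = 0, integer = TRUE)
  check_number(n, "n", lower = k, integer = TRUE)
  check_probability(p0, "p0")
  bt <- binom.test(k, n, p = p0, alternative = "two.sided")
  tibble::tibble(k = k, n = n, estimate = k / n, p0 = p0,
                 p_value = bt$p.value)
}

#' Chi-square test for two categorical labellings
#'
#' Thin wrapper around Pearson's chi-square test on the contingency table
#' of two label vectors.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
category_chisq_test <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("label vectors must align.")
  ct <- suppressWarnings(chisq.test(table(labels_a, labels_b)))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Mixed-model comparison with dendrites as random effects
#'
#' Contract wrapper around a standard linear mixed-effects routine
#' (`lmerTest::lmer`): fits `value ~ group + (1 | dendrite)` and reports
#' the fixed-effect contrasts with Bonferroni-corrected p-values
#' (`p_adj = min(1, m * p_raw)` over the m pairwise contrasts). Singular
#' fits are surfaced as a message, not hidden.
#'
#' @param data A data frame.
#' @param value,group,dendrite Columns (tidy-eval): response, fixed factor,
#'   and the dendrite grouping used as random intercept.
#' @return A list of class `mixed_model_compare` with the fitted `model`,
#'   an `effects` tibble (`contrast`, `estimate`, `se`, `df`, `p_raw`,
#'   `p_adj`) and `singular`.
#' @export
mixed_model_compare <- function(data, value, group, dendrite) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    abort("mixed_model_compare() needs the lmerTest package.")
  }
  df <- tibble::tibble(
    value = eval_tidy(enquo(value), data),
    group = as.factor(eval_tidy(enquo(group), data)),
    dendrite = as.factor(eval_tidy(enquo(dendrite), data)))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$dendrite)) < 2L) abort("need at least 2 dendrites.")
  model <- lmerTest::lmer(value ~ group + (1 | dendrite), data = df)
  singular <- lme4::isSingular(model)
  if (singular) message("mixed model fit is singular (random-effect variance ~ 0)")
  if (nlevels(df$group) > 2L && requireNamespace("emmeans", quietly = TRUE)) {
    em <- emmeans::emmeans(model, "group")
    ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
    m <- nrow(ct)
    effects <- tibble::tibble(contrast = as.character(ct$contrast),
                              estimate = ct$estimate, se = ct$SE, df = ct$df,
                              p_raw = ct$p.value,
                              p_adj = pmin(1, m * ct$p.value))
  } else {
    sm <- coef(summary(model))
    rows <- grep("^group", rownames(sm))
    m <- length(rows)
    effects <- tibble::tibble(contrast = rownames(sm)[rows],
                              estimate = sm[rows, "Estimate"],
                              se = sm[rows, "Std. Error"],
                              df = sm[rows, "df"],
                              p_raw = sm[rows, "Pr(>|t|)"],
                              p_adj = pmin(1, m * sm[rows, "Pr(>|t|)"]))
  }
  structure(list(model = model, effects = effects, singular = singular),
            class = "mixed_model_compare")
}

#' @export
print.mixed_model_compare <- function(x, ...) {
  cat("<mixed_model_compare> value ~ group + (1 | dendrite)\n")
  print(x$effects)
  invisible(x)
}
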