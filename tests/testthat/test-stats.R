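test_that("group permutation p matches the exhaustive enumeration oracle", {
  df <- tibble::tibble(v = c(0, 0, 0, 10, 10, 10),
                       g = rep(c("a", "b"), each = 3))
  # oracle: all C(6,3) = 20 label assignments, |mean diff| >= 10 in exactly 2
  combos <- combn(6, 3)
  diffs <- apply(combos, 2, function(idx) mean(df$v[idx]) - mean(df$v[-idx]))
  exact_p <- mean(abs(diffs) >= 10)
  expect_equal(exact_p, 2 / 20)

  pt <- permutation_test_groups(df, v, g, n_shuffles = 4000, seed = 2)
  expect_lt(abs(pt$p_value - exact_p), 0.02)
  expect_gte(pt$p_value, 1 / 4001)
  expect_equal(pt$observed_stat, -10)

  pt2 <- permutation_test_groups(df, v, g, n_shuffles = 4000, seed = 2)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(permutation_test_groups(df[1:3, ], v, g), "two levels")
})

test_that("permutation tests are calibrated under the null", {
  ps <- with_seed_local(10, vapply(seq_len(120), function(b) {
    d <- tibble::tibble(v = rnorm(24), g = rep(c("a", "b"), 12))
    permutation_test_groups(d, v, g, n_shuffles = 99, seed = b)$p_value
  }, numeric(1)))
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 120))
})

test_that("correlation permutation test is exact for perfect dependence", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + 1)
  pc <- permutation_correlation(d, x, y, n_shuffles = 999, seed = 3)
  expect_equal(pc$observed_stat, 1)
  expect_equal(pc$p_value, 1 / 1000)

  d2 <- dplyr::mutate(d, x = 3 * x - 7, y = -2 * y + 11)
  pc2 <- permutation_correlation(d2, x, y, n_shuffles = 999, seed = 3)
  expect_equal(abs(pc2$observed_stat), 1)
  expect_error(permutation_correlation(tibble::tibble(x = 1:5, y = rep(2, 5)),
                                       x, y), "variance")
})

test_that("binomial test agrees with direct pmf summation and the study counts", {
  expect_gt(binomial_fraction_test(10, 20)$p_value, 0.99)
  expect_lt(binomial_fraction_test(175, 929)$p_value, 0.001)

  for (n in c(7, 12, 20)) {
    for (k in c(0, 3, n %/% 2)) {
      pm <- dbinom(0:n, n, 0.5)
      oracle <- sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
      expect_equal(binomial_fraction_test(k, n)$p_value, oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("mixed models recover injected dendrite-structured effects", {
  skip_if_not_installed("lmerTest")
  sim <- with_seed_local(11, {
    dend <- rep(sprintf("d%02d", 1:17), each = 20)
    g <- rep(rep(c("resp", "unresp"), each = 10), 17)
    re <- rep(rnorm(17, 0, 0.5), each = 20)
    tibble::tibble(dendrite = dend, group = g,
                   value = re + ifelse(g == "resp", 2, 0) + rnorm(340, 0, 1))
  })
  fit <- mixed_model_compare(sim, value, group, dendrite)
  eff <- tidy(fit)
  expect_equal(nrow(eff), 1)
  expect_lt(abs(abs(eff$estimate) - 2), 2 * eff$se)
  expect_lt(eff$p_raw, 0.001)
  expect_equal(eff$p_adj, pmin(1, nrow(eff) * eff$p_raw))

  null_sim <- dplyr::mutate(sim, value = value - ifelse(group == "resp", 2, 0))
  null_fit <- mixed_model_compare(null_sim, value, group, dendrite)
  expect_gt(tidy(null_fit)$p_raw, 0.05)

  four <- dplyr::mutate(sim, group = rep(rep(c("a", "b", "c", "d"), each = 5), 17))
  f4 <- mixed_model_compare(four, value, group, dendrite)
  expect_equal(nrow(f4$effects), 6)  # all pairwise contrasts of 4 levels
  expect_equal(f4$effects$p_adj, pmin(1, 6 * f4$effects$p_raw))
})

test_that("tidiers and plots expose the fitted objects", {
  d <- tibble::tibble(v = c(rnorm(10), rnorm(10, 2)), g = rep(c("a", "b"), each = 10))
  pt <- permutation_test_groups(d, v, g, n_shuffles = 199, seed = 4)
  td <- tidy(pt)
  expect_named(td, c("statistic", "estimate", "null_mean", "null_p95",
                     "p.value", "n_shuffles", "seed"))
  expect_s3_class(glance(pt), "tbl_df")
  expect_s3_class(autoplot(pt), "ggplot")

  sched <- generate_presence_schedules(60, 5, seed = 12)
  dyn <- dynamics_summary(sched$presence)
  expect_s3_class(autoplot(dyn), "ggplot")
  expect_s3_class(plot_survival_fraction(dyn), "ggplot")
  expect_s3_class(plot_turnover(dyn), "ggplot")
  expect_s3_class(tidy(dyn, "turnover"), "tbl_df")
})

test_that("report assembly is complete, consistent and seed-deterministic", {
  e <- generate_experiment(small_config(n_spines = 24, n_sessions = 3,
                                        generate_images = TRUE,
                                        fraction_connected = 0.4, seed = 31))
  det <- suppressWarnings(detect_experiment(e, n_shuffles = 150))
  cls <- suppressWarnings(classify_across_sessions(det))
  vols <- purrr::map2_dfr(e$images, names(e$images), function(img, id) {
    v <- suppressWarnings(estimate_volume(img))
    v$spine_id <- id
    v
  })
  dists <- spine_path_distances(e$skeleton)
  rep1 <- suppressWarnings(assemble_report(cls, e$ground_truth$presence,
                                           vols, dists, det,
                                           n_shuffles = 100, seed = 5))
  expect_length(setdiff(
    c("responsive_counts", "responding_by_session", "volume_by_status",
      "volume_vs_amplitude", "distance_by_status", "categories_by_status",
      "turnover_by_status", "survival_by_status", "lifetime_by_status_category",
      "category_percentages", "volume_by_category", "distance_by_category",
      "volume_vs_n_responding", "amplitude_vs_n_responding",
      "lifetime_by_dff_category", "manifest"), names(rep1)), 0)
  expect_true(all(vapply(rep1, tibble::is_tibble, logical(1))))

  rc <- rep1$responsive_counts
  expect_equal(rc$n[rc$status == "responsive"],
               sum(cls$status == "responsive"))
  expect_equal(sum(rep1$category_percentages$percent), 100)

  rep2 <- suppressWarnings(assemble_report(cls, e$ground_truth$presence,
                                           vols, dists, det,
                                           n_shuffles = 100, seed = 5))
  expect_equal(rep1, rep2)
  expect_error(suppressWarnings(assemble_report(cls, e$ground_truth$presence,
                                                NULL, dists, det)),
               "volumes")
})
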