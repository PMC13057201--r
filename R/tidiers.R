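# broom-style tidiers for the package's result objects.

#' Tidy a permutation test
#'
#' @param x A `perm_test` from [permutation_test_groups()] or
#'   [permutation_correlation()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `estimate`, `null_mean`,
#'   `null_p95`, `p.value`, `n_shuffles`, `seed`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, estimate = x$observed_stat,
                 null_mean = x$null_mean, null_p95 = x$null_p95,
                 p.value = x$p_value, n_shuffles = x$n_shuffles, seed = x$seed)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, n_shuffles = x$n_shuffles,
                 two_sided = x$two_sided, seed = x$seed)
}

#' Tidy a mixed-model comparison
#'
#' @param x A `mixed_model_compare` object.
#' @param ... Unused.
#' @return The contrasts tibble (`contrast`, `estimate`, `se`, `df`,
#'   `p_raw`, `p_adj`).
#' @export
tidy.mixed_model_compare <- function(x, ...) x$effects

#' @rdname tidy.mixed_model_compare
#' @export
glance.mixed_model_compare <- function(x, ...) {
  tibble::tibble(singular = x$singular,
                 sigma = stats::sigma(x$model),
                 logLik = as.numeric(stats::logLik(x$model)),
                 n_obs = stats::nobs(x$model))
}

#' Tidy a dynamics summary
#'
#' @param x A `dynamics_summary`.
#' @param table Which table to return.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.dynamics_summary <- function(x, table = c("categories", "turnover",
                                               "survival", "lifetime"), ...) {
  x[[match.arg(table)]]
}

#' @rdname tidy.dynamics_summary
#' @export
glance.dynamics_summary <- function(x, ...) {
  tibble::tibble(n_spines = length(unique(x$lifetime$spine_id)),
                 n_sessions = length(x$session_days),
                 mean_lifetime_days = mean(x$lifetime$lifetime_days))
}
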