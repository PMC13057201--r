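# Figure-ready summary tables tying the modules together.

#' Assemble figure-ready summary tables
#'
#' Combines detection, classification, presence, volume and distance
#' results into tidy tables mirroring the headline analyses: responsive
#' fractions, volume and proximity by status, volume-amplitude coupling,
#' longitudinal category fractions, turnover, survival, lifetimes and the
#' maximal-dF/F percentile categories. All permutation p-values derive
#' from `seed`; a rerun with the same inputs and seed is identical.
#'
#' @param classification Per-spine tibble from [classify_across_sessions()].
#' @param presence Tidy presence tibble (`spine_id`, `session`, `present`).
#' @param volumes Tibble `spine_id`, `volume` from [estimate_volume()].
#' @param distances Symmetric path-distance matrix from
#'   [spine_path_distances()].
#' @param detections Detection tibble from [detect_experiment()].
#' @param session_days Day labels (default 0, 4, ... per session).
#' @param n_shuffles,seed Permutation parameters for the embedded tests.
#' @return A named list of class `analysis_report` of tibbles, plus a
#'   `manifest` with seed and input sizes.
#' @export
assemble_report <- function(classification, presence, volumes, distances,
                            detections, session_days = NULL,
                            n_shuffles = 1000L, seed = 1L) {
  missing_in <- c(classification = is.null(classification),
                  presence = is.null(presence), volumes = is.null(volumes),
                  distances = is.null(distances), detections = is.null(detections))
  if (any(missing_in)) {
    abort(paste("missing report inputs:",
                paste(names(missing_in)[missing_in], collapse = ", ")))
  }
  cls <- dplyr::left_join(classification, volumes, by = "spine_id")
  status_tbl <- cls[, c("spine_id", "status")]
  dyn <- dynamics_summary(presence, session_days = session_days,
                          status = status_tbl)
  dyn_all <- dynamics_summary(presence, session_days = session_days)
  cat_tbl <- classify_spine_dynamics(presence)
  cls <- dplyr::left_join(cls, cat_tbl[, c("spine_id", "category")], by = "spine_id")
  cls <- dplyr::left_join(cls,
                          dyn$lifetime[, c("spine_id", "lifetime_days")],
                          by = "spine_id")
  resp <- cls[cls$status == "responsive", , drop = FALSE]

  n_resp <- sum(cls$status == "responsive")
  ord <- match(rownames(distances), cls$spine_id)
  dist_status <- as.character(cls$status)[ord]
  dist_cat <- as.character(cls$category)[ord]

  tables <- list(
    responsive_counts = dplyr::mutate(
      dplyr::count(cls, .data$status),
      fraction = .data$n / sum(.data$n),
      binomial_p = binomial_fraction_test(n_resp, nrow(cls))$p_value),
    responding_by_session = detections |>
      dplyr::filter(.data$roi_kind == "spine") |>
      dplyr::group_by(.data$session) |>
      dplyr::summarise(n_responding = sum(.data$responding, na.rm = TRUE),
                       n_spines = sum(!is.na(.data$responding)),
                       fraction = .data$n_responding / .data$n_spines,
                       .groups = "drop"),
    volume_by_status = dplyr::summarise(
      dplyr::group_by(cls, .data$status),
      n = dplyr::n(), mean_volume = mean(.data$volume, na.rm = TRUE),
      median_volume = median(.data$volume, na.rm = TRUE), .groups = "drop") |>
      dplyr::mutate(perm_p = tidy(permutation_test_groups(
        cls, .data$volume, .data$status, n_shuffles = n_shuffles,
        seed = derive_seed(seed, 11L)))$p.value),
    volume_vs_amplitude = tidy(permutation_correlation(
      resp, .data$volume, .data$max_dff, n_shuffles = n_shuffles,
      seed = derive_seed(seed, 12L))),
    distance_by_status = pairwise_distance_summary(
      distances, dist_status, n_shuffles = n_shuffles,
      seed = derive_seed(seed, 13L)),
    categories_by_status = dyn$categories,
    turnover_by_status = dyn$turnover,
    survival_by_status = dyn$survival,
    lifetime_by_status_category = dyn$lifetime |>
      dplyr::group_by(.data$status, .data$category) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_lifetime_days = mean(.data$lifetime_days),
                       .groups = "drop"),
    category_percentages = dplyr::mutate(
      dyn_all$categories[, c("category", "n")],
      percent = 100 * .data$n / sum(.data$n)),
    volume_by_category = cls |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_volume = mean(.data$volume, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(perm_p_vs_rest = tidy(permutation_test_groups(
        dplyr::mutate(cls, is_persistent = .data$category == "persistent"),
        .data$volume, .data$is_persistent, n_shuffles = n_shuffles,
        seed = derive_seed(seed, 14L)))$p.value),
    distance_by_category = pairwise_distance_summary(
      distances, dist_cat, n_shuffles = n_shuffles,
      seed = derive_seed(seed, 15L)),
    volume_vs_n_responding = tidy(permutation_correlation(
      resp, .data$volume, .data$n_responding_sessions,
      n_shuffles = n_shuffles, seed = derive_seed(seed, 16L))),
    amplitude_vs_n_responding = tidy(permutation_correlation(
      resp, .data$max_dff, .data$n_responding_sessions,
      n_shuffles = n_shuffles, seed = derive_seed(seed, 17L))),
    lifetime_by_dff_category = cls |>
      dplyr::group_by(.data$dff_category) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_lifetime_days = mean(.data$lifetime_days),
                       .groups = "drop")
  )
  structure(c(tables,
              list(manifest = tibble::tibble(
                seed = seed, n_shuffles = n_shuffles,
                n_spines = nrow(cls), n_responsive = n_resp,
                n_sessions = length(unique(presence$session))))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> tables:\n ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
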