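# Longitudinal spine bookkeeping: survival-sequence categories, turnover
# ratio, survival fraction, lifetime, recurrence and density.

#' Classify a presence sequence into a longitudinal category
#'
#' Categories follow the survival-sequence rules used for chronically imaged
#' spines: *persistent* spines are present on all recording days; *formed*
#' spines appear during the series and stay until the end (a spine present
#' only in the final session is formed); *eliminated* spines are present
#' from the first session, disappear, and never reappear; everything else —
#' any gap, or a late appearance followed by disappearance — is *transient*.
#'
#' @param presence Logical vector of per-session presence (length >= 2,
#'   at least one `TRUE`).
#' @return One of `"persistent"`, `"transient"`, `"formed"`, `"eliminated"`.
#' @export
classify_survival <- function(presence) {
  presence <- as.logical(presence)
  if (length(presence) < 2L) abort("need at least two sessions")
  if (!any(presence)) abort("all-absent presence sequence")
  n <- length(presence)
  first <- which(presence)[1L]
  last <- which(presence)[length(which(presence))]
  gapless <- all(presence[first:last])
  if (all(presence)) return("persistent")
  if (first > 1L && last == n && gapless) return("formed")
  if (first == 1L && last < n && gapless) return("eliminated")
  "transient"
}

#' Classify every spine in a tidy presence table
#'
#' @param presence Tibble with columns `spine_id`, `session`, `present`
#'   (and optionally `dendrite_id`, carried through).
#' @return Tibble with one row per spine: `spine_id`, `category` (factor
#'   persistent/transient/formed/eliminated), plus `dendrite_id` if given.
#' @export
classify_spine_dynamics <- function(presence) {
  stopifnot(all(c("spine_id", "session", "present") %in% names(presence)))
  lv <- c("persistent", "transient", "formed", "eliminated")
  out <- presence |>
    dplyr::arrange(.data$spine_id, .data$session) |>
    dplyr::group_by(.data$spine_id) |>
    dplyr::summarise(
      category = classify_survival(.data$present),
      n_present = sum(.data$present),
      flips = count_flips(.data$present),
      recurrent = is_recurrent(.data$present),
      .groups = "drop") |>
    dplyr::mutate(category = factor(.data$category, levels = lv))
  if ("dendrite_id" %in% names(presence)) {
    map <- dplyr::distinct(presence, .data$spine_id, .data$dendrite_id)
    out <- dplyr::left_join(out, map, by = "spine_id")
  }
  out
}

#' Turnover ratio between two consecutive sessions
#'
#' `(formed + eliminated) / mean(present at t, present at t + 1)`, where
#' formed spines are absent at `t` and present at `t + 1` and eliminated
#' spines the reverse. The mean denominator keeps the ratio in `[0, 2]` and
#' symmetric in formation and elimination.
#'
#' @param present_t,present_t1 Logical presence vectors for the same spines
#'   at two consecutive sessions.
#' @return Turnover ratio (scalar in `[0, 2]`).
#' @export
turnover_ratio <- function(present_t, present_t1) {
  if (length(present_t) != length(present_t1)) {
    abort("presence vectors must align spine-for-spine")
  }
  formed <- sum(!present_t & present_t1)
  eliminated <- sum(present_t & !present_t1)
  denom <- (sum(present_t) + sum(present_t1)) / 2
  if (denom == 0) abort("no spines present in either session")
  (formed + eliminated) / denom
}

#' Survival fraction of the first-session cohort
#'
#' Fraction of the spines present in the first session that are still
#' continuously present in every session up to and including session `t`.
#' Equals 1 at the first session and is monotone nonincreasing.
#'
#' @param presence_matrix Logical spines x sessions matrix.
#' @param t Session index (1-based).
#' @return Survival fraction in `[0, 1]`.
#' @export
survival_fraction <- function(presence_matrix, t) {
  presence_matrix <- as.matrix(presence_matrix)
  check_number(t, "t", lower = 1, upper = ncol(presence_matrix), integer = TRUE)
  cohort <- presence_matrix[, 1L]
  if (!any(cohort)) abort("no spines present in the first session")
  kept <- rowSums(!presence_matrix[, seq_len(t), drop = FALSE]) == 0L
  sum(cohort & kept) / sum(cohort)
}

#' Appearance/disappearance dynamics of a single spine
#'
#' `count_flips()` counts state changes between consecutive sessions;
#' `is_recurrent()` is `TRUE` when the spine has two or more disjoint runs
#' of presence (it disappeared and came back); `lifetime_days()` is the
#' cumulative observed lifetime, sessions-present times the imaging
#' interval.
#'
#' @param presence Logical per-session presence vector.
#' @param session_interval_days Days between imaging sessions (default 4).
#' @return `count_flips()`: integer; `is_recurrent()`: logical;
#'   `lifetime_days()`: days.
#' @export
count_flips <- function(presence) {
  presence <- as.logical(presence)
  sum(diff(presence) != 0L)
}

#' @rdname count_flips
#' @export
is_recurrent <- function(presence) {
  presence <- as.logical(presence)
  r <- rle(presence)
  sum(r$values) >= 2L
}

#' @rdname count_flips
#' @export
lifetime_days <- function(presence, session_interval_days = 4) {
  check_number(session_interval_days, "session_interval_days", lower = 1e-9)
  sum(as.logical(presence)) * session_interval_days
}

#' Spine density
#'
#' @param n_spines_present Number of spines present on the segment.
#' @param dendrite_length_um Segment length in micrometres (> 0).
#' @return Density in spines per micrometre.
#' @export
spine_density <- function(n_spines_present, dendrite_length_um) {
  check_number(dendrite_length_um, "dendrite_length_um", lower = .Machine$double.eps)
  n_spines_present / dendrite_length_um
}

#' Longitudinal dynamics summary of a presence table
#'
#' Computes, optionally stratified by a per-spine grouping (e.g. the
#' responsive/unresponsive status) and by dendrite: the four category
#' fractions, the turnover ratio per inter-session interval, the survival
#' fraction per session, per-spine lifetimes, and spine density per session
#' when dendrite lengths are supplied.
#'
#' @param presence Tidy presence tibble (`spine_id`, `session`, `present`,
#'   optionally `dendrite_id`).
#' @param session_days Day labels of the sessions (default `c(0,4,8,12,16)`
#'   truncated to the number of sessions).
#' @param status Optional tibble (`spine_id`, `status`) used to stratify.
#' @param dendrite_lengths Optional tibble (`dendrite_id`, `length_um`).
#' @return A list of class `dynamics_summary` with tibbles `categories`,
#'   `turnover`, `survival`, `lifetime` and (optionally) `density`.
#' @export
dynamics_summary <- function(presence, session_days = NULL, status = NULL,
                             dendrite_lengths = NULL) {
  sessions <- sort(unique(presence$session))
  ns <- length(sessions)
  session_days <- session_days %||% (seq_len(ns) - 1L) * 4L
  if (length(session_days) != ns) abort("`session_days` must match the sessions")
  pres <- presence
  if (!is.null(status)) {
    pres <- dplyr::left_join(pres, status, by = "spine_id")
  } else {
    pres$status <- factor("all")
  }
  cls <- classify_spine_dynamics(presence)
  cls <- dplyr::left_join(cls, dplyr::distinct(pres, .data$spine_id, .data$status),
                          by = "spine_id")

  categories <- cls |>
    dplyr::count(.data$status, .data$category, .drop = FALSE) |>
    dplyr::group_by(.data$status) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  wide_by_status <- function(df) {
    split(df, df$status, drop = TRUE)
  }
  mat_of <- function(df) {
    w <- tidyr::pivot_wider(df[, c("spine_id", "session", "present")],
                            names_from = "session", values_from = "present")
    as.matrix(w[, as.character(sessions), drop = FALSE])
  }
  turnover <- purrr::imap_dfr(wide_by_status(pres), function(df, st) {
    m <- mat_of(df)
    purrr::map_dfr(seq_len(ns - 1L), function(t) {
      tibble::tibble(status = st,
                     from_day = session_days[t], to_day = session_days[t + 1L],
                     turnover = turnover_ratio(m[, t], m[, t + 1L]))
    })
  })
  survival <- purrr::imap_dfr(wide_by_status(pres), function(df, st) {
    m <- mat_of(df)
    tibble::tibble(status = st, day = session_days,
                   survival = vapply(seq_len(ns), function(t)
                     survival_fraction(m, t), numeric(1)))
  })
  lifetime <- pres |>
    dplyr::group_by(.data$spine_id, .data$status) |>
    dplyr::summarise(lifetime_days = lifetime_days(
      .data$present[order(.data$session)],
      session_interval_days = if (ns > 1) diff(session_days)[1] else 4),
      .groups = "drop") |>
    dplyr::left_join(cls[, c("spine_id", "category")], by = "spine_id")

  out <- list(categories = categories, turnover = turnover,
              survival = survival, lifetime = lifetime,
              session_days = session_days)
  if (!is.null(dendrite_lengths) && "dendrite_id" %in% names(presence)) {
    out$density <- presence |>
      dplyr::group_by(.data$dendrite_id, .data$session) |>
      dplyr::summarise(n_present = sum(.data$present), .groups = "drop") |>
      dplyr::left_join(dendrite_lengths, by = "dendrite_id") |>
      dplyr::mutate(density = .data$n_present / .data$length_um)
  }
  structure(out, class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat("<dynamics_summary>\n")
  cat("Category fractions:\n")
  print(x$categories, n = 8)
  invisible(x)
}
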