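# Permutation-null detection of optogenetically evoked EPSCaTs at neuron,
# dendrite and spine level, with removal of back-propagating dendritic
# contamination from spine traces.

#' Remove the dendritic component from a spine trace
#'
#' Fits `spine = alpha + beta * dendrite` with an iteratively reweighted
#' robust linear estimator (Huber loss, tuning constant 1.345) and returns
#' the residual. Robustness keeps sparse synaptic transients from dragging
#' the fit; `beta` is clipped at zero because dendritic contamination cannot
#' be negative. Falls back to ordinary least squares with a warning when the
#' robust fit does not converge.
#'
#' @param spine,dendrite dF/F traces of equal length.
#' @param k Huber tuning constant.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance.
#' @return The residual trace, with attributes `coefficients`
#'   (`c(alpha, beta)`) and `converged`.
#' @export
remove_dendritic_component <- function(spine, dendrite, k = 1.345,
                                       max_iter = 50L, tol = 1e-8) {
  if (length(spine) != length(dendrite)) {
    abort("`spine` and `dendrite` must have the same length.")
  }
  if (any(!is.finite(spine)) || any(!is.finite(dendrite))) {
    abort("traces must be finite.")
  }
  fit_coefs <- function(formula_env) {
    converged <- TRUE
    fit <- withCallingHandlers(
      MASS::rlm(formula_env, psi = MASS::psi.huber, k = k,
                maxit = max_iter, acc = tol),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(coef = coef(fit), converged = converged)
  }
  if (sd(dendrite) < .Machine$double.eps^0.5) {
    ab <- c(mean(spine), 0)
    conv <- TRUE
  } else if (sd(resid(ols <- lm(spine ~ dendrite))) < 1e-10) {
    # exact affine relation: IRLS has zero scale, OLS is already the answer
    ab <- unname(coef(ols))
    conv <- TRUE
  } else {
    res <- tryCatch(fit_coefs(spine ~ dendrite), error = function(e) NULL)
    if (is.null(res)) {
      warn("robust regression failed; falling back to ordinary least squares")
      ab <- unname(coef(lm(spine ~ dendrite)))
      conv <- FALSE
    } else {
      if (!res$converged) {
        warn("robust regression did not converge; falling back to ordinary least squares")
        res$coef <- coef(lm(spine ~ dendrite))
      }
      ab <- unname(res$coef)
      conv <- res$converged
    }
    if (ab[2] < 0) { # contamination cannot be negative
      loc <- tryCatch(MASS::rlm(spine ~ 1, psi = MASS::psi.huber, k = k,
                                maxit = max_iter, acc = tol),
                      warning = function(w) NULL, error = function(e) NULL)
      ab <- c(if (is.null(loc)) mean(spine) else unname(coef(loc)[1]), 0)
    }
  }
  out <- spine - (ab[1] + ab[2] * dendrite)
  attr(out, "coefficients") <- c(alpha = ab[1], beta = ab[2])
  attr(out, "converged") <- conv
  out
}

#' Boxcar smoothing
#'
#' Centred moving average with reflect padding at the edges; the trace
#' length is preserved. A 5-bin boxcar is the default used to suppress
#' high-frequency noise before detection.
#'
#' @param trace Numeric trace.
#' @param width Odd window width (bins).
#' @return Smoothed trace of the same length.
#' @export
smooth_boxcar <- function(trace, width = 5L) {
  check_number(width, "width", lower = 1, integer = TRUE)
  if (width %% 2L == 0L) abort("`width` must be odd.")
  as.vector(rowwise_boxcar(matrix(trace, nrow = 1L), as.integer(width)))
}

# Eligible 0-based pseudo-onsets: the full window must fit inside the trace
# and the onset frame must be motion-free.
eligible_onsets <- function(n_frames, window, motion_flags = NULL) {
  post <- window$stim_frames + window$response_frames
  o <- seq.int(window$baseline_frames, n_frames - post)
  if (!is.null(motion_flags)) o <- o[!motion_flags[o + 1L]]
  o
}

# Shared core: per-timepoint 95th-percentile threshold of the
# pseudo-trial-averaged trace over shuffles.
perm_null_core <- function(sm_trace, n_trials, window, n_shuffles, seed,
                           motion_flags = NULL, level = 0.95) {
  elig <- eligible_onsets(length(sm_trace), window, motion_flags)
  if (length(elig) < max(10L, n_trials)) {
    abort(sprintf("only %d eligible motion-free onsets available for %d pseudo-trials",
                  length(elig), n_trials))
  }
  e <- rebaseline_rows(cut_windows(sm_trace, elig, window), window)
  s <- with_seed(seed,
                 matrix(sample.int(length(elig), n_shuffles * n_trials, replace = TRUE),
                        nrow = n_shuffles))
  g <- rep(seq_len(n_shuffles), times = n_trials)
  means <- rowsum(e[as.vector(s), , drop = FALSE], g) / n_trials
  threshold <- apply(means, 2L, quantile, probs = level, names = FALSE)
  list(threshold = threshold, n_eligible = length(elig))
}

#' Permutation null for evoked-transient detection
#'
#' Builds the null distribution of the trial-averaged response by permuting
#' the stimulation onset to random motion-free locations of the session
#' trace: for each of `n_shuffles` shuffles, `n_trials` pseudo-onsets are
#' drawn with replacement, their windows cut and re-baselined exactly like
#' real trials, and averaged. The returned threshold trace is, at each
#' aligned timepoint, the 95th percentile of the pseudo-trial-averaged
#' dF/F over shuffles.
#'
#' @param trace Processed continuous dF/F-scale trace (after dendritic
#'   subtraction and boxcar smoothing, where applicable).
#' @param n_trials Number of pseudo-trials per shuffle (match the real
#'   usable-trial count).
#' @param window A [trial_window()].
#' @param n_shuffles Number of shuffles (default 10000).
#' @param seed Integer seed; the null is fully seed-deterministic.
#' @param motion_flags Optional logical per-frame flags; flagged frames are
#'   not used as pseudo-onsets.
#' @param level Percentile of the null (default 0.95).
#' @return A list of class `permutation_null` with `threshold` (one value
#'   per aligned window timepoint) and `n_eligible`.
#' @export
build_permutation_null <- function(trace, n_trials, window = trial_window(),
                                   n_shuffles = 10000L, seed = 1L,
                                   motion_flags = NULL, level = 0.95) {
  check_number(n_trials, "n_trials", lower = 5, integer = TRUE)
  check_number(n_shuffles, "n_shuffles", lower = 1, integer = TRUE)
  out <- perm_null_core(trace, n_trials, window, n_shuffles, seed,
                        motion_flags, level)
  structure(c(out, list(window = window, n_shuffles = n_shuffles, seed = seed)),
            class = "permutation_null")
}

#' Classify a trial-averaged response against a permutation null
#'
#' A response is called when the trial-averaged trace exceeds the
#' per-timepoint null threshold (strictly) in more than `required_fraction`
#' of the stimulation-window timepoints: 0.5 for neurons, 0.3 for dendrites
#' and spines.
#'
#' @param mean_trace Trial-averaged aligned dF/F trace (one value per
#'   window timepoint).
#' @param threshold_trace Null threshold from [build_permutation_null()]
#'   (a `permutation_null` or a numeric vector).
#' @param window A [trial_window()].
#' @param required_fraction Fraction of significant stimulation timepoints
#'   required.
#' @return A one-row tibble with `responding` and `sig_timepoint_fraction`.
#' @export
classify_response <- function(mean_trace, threshold_trace,
                              window = trial_window(), required_fraction = 0.3) {
  if (inherits(threshold_trace, "permutation_null")) {
    threshold_trace <- threshold_trace$threshold
  }
  check_probability(required_fraction, "required_fraction")
  stim_idx <- window$baseline_frames + seq_len(window$stim_frames)
  if (max(stim_idx) > length(mean_trace) || length(mean_trace) != length(threshold_trace)) {
    abort("stimulation window falls outside the aligned traces.")
  }
  frac <- mean(mean_trace[stim_idx] > threshold_trace[stim_idx])
  tibble::tibble(responding = frac > required_fraction,
                 sig_timepoint_fraction = frac)
}

#' EPSCaT amplitude of a trial-averaged response
#'
#' Maximum of the boxcar-smoothed trial-averaged dF/F within the
#' stimulation window extended by the post-stimulus response frames
#' (0.5 s by default).
#'
#' @inheritParams classify_response
#' @return Amplitude in dF/F units.
#' @export
epscat_amplitude <- function(mean_trace, window = trial_window()) {
  idx <- window$baseline_frames +
    seq_len(window$stim_frames + window$response_frames)
  idx <- idx[idx <= length(mean_trace)]
  max(mean_trace[idx])
}

# Full single-ROI, single-session detection. `f` is the raw fluorescence
# trace; `dendrite_f` enables robust dendritic subtraction (spines);
# `neuropil_f` enables neuropil correction (neurons).
detect_roi <- function(f, onsets, motion, window, required_fraction,
                       n_shuffles, seed, dendrite_f = NULL, neuropil_f = NULL,
                       neuropil_coefficient = 0.7, smooth_width = 5L,
                       stable_fraction = 0.7, min_trials = 5L) {
  if (!is.null(neuropil_f)) f <- neuropil_correct(f, neuropil_f, neuropil_coefficient)
  usable <- select_trials(motion, onsets, window, stable_fraction)
  if (length(usable) < min_trials) {
    return(list(responding = NA, sig_timepoint_fraction = NA_real_,
                amplitude = NA_real_, n_trials_used = length(usable),
                mean_trace = NULL, threshold = NULL,
                coefficients = c(alpha = NA_real_, beta = NA_real_)))
  }
  use_onsets <- onsets[usable]
  base_frames <- as.vector(outer(use_onsets, seq.int(-window$baseline_frames, -1L), "+")) + 1L
  base_frames <- base_frames[!motion[base_frames]]
  to_dff <- function(x) {
    f0 <- mean(x[base_frames])
    if (!is.finite(f0) || f0 <= 0) abort("non-positive session baseline F0")
    x / f0 - 1
  }
  # Boxcar smoothing is linear, so it commutes with the affine dendritic
  # subtraction; fitting the robust regression on the smoothed traces keeps
  # the rare high-leverage dendritic-event frames from being Huber-
  # downweighted against raw frame noise (which would leak contamination).
  sm <- smooth_boxcar(to_dff(f), smooth_width)
  ab <- c(alpha = 0, beta = 0)
  if (!is.null(dendrite_f)) {
    sm_d <- smooth_boxcar(to_dff(dendrite_f), smooth_width)
    # The coupling coefficient is only identifiable where the dendrite is
    # active; restricting the robust fit to dendrite-active frames avoids
    # the attenuation that noise-dominated frames (and Huber downweighting
    # of the rare event frames) would otherwise cause. No appreciable
    # dendritic activity means there is nothing to subtract (beta = 0).
    noise_d <- stats::mad(sm_d)
    active <- which(sm_d > 5 * noise_d)
    if (length(active) >= 15L) {
      res_fit <- remove_dendritic_component(sm[active], sm_d[active])
      ab <- attr(res_fit, "coefficients")
      sm <- sm - ab[["beta"]] * sm_d # windows are re-baselined; alpha is moot
    }
  }
  w <- rebaseline_rows(cut_windows(sm, use_onsets, window), window)
  mean_trace <- colMeans(w)
  null <- perm_null_core(sm, length(usable), window, n_shuffles, seed, motion)
  cls <- classify_response(mean_trace, null$threshold, window, required_fraction)
  list(responding = cls$responding,
       sig_timepoint_fraction = cls$sig_timepoint_fraction,
       amplitude = epscat_amplitude(mean_trace, window),
       n_trials_used = length(usable),
       mean_trace = mean_trace, threshold = null$threshold,
       coefficients = ab)
}

#' Detect evoked transients across a whole synthetic experiment
#'
#' Runs the detection pipeline — trial gating, dF/F conversion, robust
#' dendritic subtraction (spines only), boxcar smoothing, trial averaging,
#' permutation null, significance criterion — for every dendrite and every
#' present spine in every session of a [generate_experiment()] result.
#' Each (session, ROI) pair gets its own derived seed, so results are
#' reproducible independently of processing order.
#'
#' @param experiment A `spine_experiment`.
#' @param window A [trial_window()]; defaults to the window implied by the
#'   experiment's protocol.
#' @param n_shuffles Shuffles for the permutation null.
#' @param seed Master seed (defaults to the experiment's).
#' @param required_fraction Significant-timepoint fraction required for
#'   dendrites and spines (default 0.3).
#' @param smooth_width Boxcar width.
#' @param stable_fraction,min_trials Trial-gating parameters.
#' @param rois Optional character vector restricting detection to given
#'   `roi_id`s.
#' @return A tibble with one row per ROI x session: `session`, `roi_id`,
#'   `roi_kind`, `dendrite_id`, `responding`, `sig_timepoint_fraction`,
#'   `amplitude`, `n_trials_used`, `n_shuffles`, `seed`.
#' @export
detect_experiment <- function(experiment, window = NULL, n_shuffles = 10000L,
                              seed = NULL, required_fraction = 0.3,
                              smooth_width = 5L, stable_fraction = 0.7,
                              min_trials = 5L, rois = NULL) {
  stopifnot(inherits(experiment, "spine_experiment"))
  window <- window %||% default_window(experiment$config)
  seed <- seed %||% experiment$config$seed
  gt <- experiment$ground_truth
  out <- list()
  for (ss in experiment$sessions) {
    info <- ss$roi_info
    present <- gt$presence$spine_id[gt$presence$session == ss$session & gt$presence$present]
    todo <- info[info$roi_kind %in% c("spine", "dendrite"), , drop = FALSE]
    todo <- todo[todo$roi_kind == "dendrite" | todo$roi_id %in% present, , drop = FALSE]
    if (!is.null(rois)) todo <- todo[todo$roi_id %in% rois, , drop = FALSE]
    for (i in seq_len(nrow(todo))) {
      roi <- todo$roi_id[i]
      kind <- todo$roi_kind[i]
      roi_stream <- match(roi, info$roi_id)  # stable across ROI subsets
      dend_f <- if (kind == "spine") ss$F[, todo$dendrite_id[i]] else NULL
      r <- detect_roi(ss$F[, roi], ss$onset_frames, ss$motion, window,
                      required_fraction, n_shuffles,
                      seed = derive_seed(seed, ss$session * 100003L + roi_stream),
                      dendrite_f = dend_f, smooth_width = smooth_width,
                      stable_fraction = stable_fraction, min_trials = min_trials)
      out[[length(out) + 1L]] <- tibble::tibble(
        session = ss$session, roi_id = roi, roi_kind = kind,
        dendrite_id = todo$dendrite_id[i],
        responding = r$responding,
        sig_timepoint_fraction = r$sig_timepoint_fraction,
        amplitude = r$amplitude, n_trials_used = r$n_trials_used,
        n_shuffles = as.integer(n_shuffles),
        seed = derive_seed(seed, ss$session * 100003L + roi_stream))
    }
  }
  dplyr::bind_rows(out)
}

#' Detect evoked transients from tidy trace tables
#'
#' Data-frame-first interface to the same pipeline as
#' [detect_experiment()]: takes traces in the tidy schema (`session`,
#' `roi_id`, `roi_kind`, `frame`, `fluorescence`, `motion_flag`, optionally
#' `dendrite_id`) plus a trial table (`session`, `trial`, `onset_frame`).
#' When no `dendrite_id` column is present, all spines are paired with the
#' single dendrite ROI of their session.
#'
#' @param traces Tidy trace tibble.
#' @param trials Trial-onset tibble.
#' @inheritParams detect_experiment
#' @return As [detect_experiment()].
#' @export
detect_session <- function(traces, trials, window = trial_window(),
                           n_shuffles = 10000L, seed = 1L,
                           required_fraction = 0.3, smooth_width = 5L,
                           stable_fraction = 0.7, min_trials = 5L) {
  needed <- c("session", "roi_id", "roi_kind", "frame", "fluorescence", "motion_flag")
  if (!all(needed %in% names(traces))) {
    abort(paste("`traces` must have columns:", paste(needed, collapse = ", ")))
  }
  out <- list()
  for (s in sort(unique(traces$session))) {
    tr <- traces[traces$session == s, , drop = FALSE]
    onsets <- sort(trials$onset_frame[trials$session == s])
    wide <- split(tr[order(tr$frame), ], tr$roi_id[order(tr$frame)])
    motion <- wide[[1L]]$motion_flag
    kinds <- vapply(wide, function(d) d$roi_kind[1L], character(1))
    dend_ids <- names(kinds)[kinds == "dendrite"]
    dend_of <- function(roi) {
      if ("dendrite_id" %in% names(tr)) {
        tr$dendrite_id[tr$roi_id == roi][1L]
      } else if (length(dend_ids) == 1L) {
        dend_ids
      } else {
        abort("multiple dendrite ROIs: traces need a `dendrite_id` column")
      }
    }
    i <- 0L
    for (roi in names(wide)[kinds %in% c("spine", "dendrite")]) {
      i <- i + 1L
      kind <- kinds[[roi]]
      dend <- if (kind == "spine") dend_of(roi) else NA_character_
      r <- detect_roi(wide[[roi]]$fluorescence, onsets, motion, window,
                      required_fraction, n_shuffles,
                      seed = derive_seed(seed, s * 100003L + i),
                      dendrite_f = if (kind == "spine") wide[[dend]]$fluorescence,
                      smooth_width = smooth_width,
                      stable_fraction = stable_fraction, min_trials = min_trials)
      out[[length(out) + 1L]] <- tibble::tibble(
        session = s, roi_id = roi, roi_kind = kind, dendrite_id = dend,
        responding = r$responding,
        sig_timepoint_fraction = r$sig_timepoint_fraction,
        amplitude = r$amplitude, n_trials_used = r$n_trials_used,
        n_shuffles = as.integer(n_shuffles),
        seed = derive_seed(seed, s * 100003L + i))
    }
  }
  dplyr::bind_rows(out)
}

#' Classify spines as responsive or unresponsive across sessions
#'
#' A spine is responsive if evoked transients were detected in at least one
#' session and unresponsive if none were detected in any session. Also
#' records the number of responding sessions, the maximal measured dF/F
#' across sessions and its percentile category (see
#' [assign_dff_categories()]).
#'
#' @param detections Detection tibble from [detect_experiment()] or
#'   [detect_session()].
#' @return A tibble with one row per spine: `spine_id`, per-session counts,
#'   `status` (factor responsive/unresponsive), `n_responding_sessions`,
#'   `max_dff`, `dff_category`.
#' @export
classify_across_sessions <- function(detections) {
  sp <- detections
  if ("roi_kind" %in% names(sp)) sp <- sp[sp$roi_kind == "spine", , drop = FALSE]
  if (nrow(sp) == 0L) abort("no spine detections to classify")
  out <- sp |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      dendrite_id = dplyr::first(.data$dendrite_id),
      n_sessions = dplyr::n(),
      n_responding_sessions = sum(.data$responding, na.rm = TRUE),
      max_dff = if (all(is.na(.data$amplitude))) NA_real_ else
        max(.data$amplitude, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::rename(spine_id = "roi_id") |>
    dplyr::mutate(status = factor(ifelse(.data$n_responding_sessions >= 1L,
                                         "responsive", "unresponsive"),
                                  levels = c("responsive", "unresponsive")))
  out$dff_category <- assign_dff_categories(out$max_dff)
  out
}

#' Percentile categories of maximal dF/F
#'
#' Cuts maximal fluorescence transients at the 25th, 50th, 75th and 95th
#' percentiles of all spines into five categories: lowest (below the 25th
#' percentile), low, mid, high, and highest (strictly above the 95th
#' percentile). Intervals are lower-closed/upper-open; if the quantiles
#' collapse (all values identical) every spine lands in `lowest`.
#'
#' @param max_dff Numeric vector of per-spine maximal dF/F.
#' @return Factor with levels lowest, low, mid, high, highest.
#' @export
assign_dff_categories <- function(max_dff) {
  lv <- c("lowest", "low", "mid", "high", "highest")
  ok <- is.finite(max_dff)
  out <- factor(rep(NA_character_, length(max_dff)), levels = lv)
  if (!any(ok)) return(out)
  if (sum(ok) < 20L) {
    warn("fewer than 20 spines: percentile categories are unstable")
  }
  q <- quantile(max_dff[ok], c(0.25, 0.5, 0.75, 0.95), names = FALSE)
  if (q[1] == q[4]) { # degenerate: quantiles collapse
    out[ok] <- "lowest"
    return(out)
  }
  x <- max_dff[ok]
  lab <- ifelse(x < q[1], "lowest",
         ifelse(x < q[2], "low",
         ifelse(x < q[3], "mid",
         ifelse(x <= q[4], "high", "highest"))))
  out[ok] <- lab
  out
}
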