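# Synthetic experiment generator: ground-truth-annotated fluorescence traces,
# presence schedules, skeletons and labelled volume images with the
# statistical structure the analysis pipeline assumes.

# Difference-of-exponentials indicator kernel, peak-normalised to 1.
epscat_kernel <- function(frame_rate, rise_tau, decay_tau) {
  t <- seq(0, 4 * decay_tau, by = 1 / frame_rate)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k / max(k)
}

# Add amp * kernel starting at 0-based frame `at` to signal `x` in place.
add_kernel_events <- function(x, at, amps, kernel) {
  n <- length(x)
  kl <- length(kernel)
  for (i in seq_along(at)) {
    lo <- at[i] + 1L
    hi <- min(n, at[i] + kl)
    if (lo <= n) x[lo:hi] <- x[lo:hi] + amps[i] * kernel[seq_len(hi - lo + 1L)]
  }
  x
}

#' Generate multi-session presence schedules with known dynamic categories
#'
#' Draws one longitudinal category per spine (persistent, transient, formed,
#' eliminated) and emits a presence schedule consistent with that category
#' under the survival-sequence rules of [classify_survival()]. Spines flagged
#' responsive can be biased towards persistence via an odds multiplier,
#' emulating the association between functional connectivity and stability.
#'
#' @param n_spines Number of spines.
#' @param n_sessions Number of imaging sessions (>= 2).
#' @param category_probs 4 probabilities (persistent, transient, formed,
#'   eliminated), summing to 1.
#' @param seed Integer seed.
#' @param responsive Optional logical vector (length `n_spines`); spines
#'   marked `TRUE` get the persistent-category odds multiplied.
#' @param persistence_odds_multiplier Multiplier (>= 0) applied to the
#'   persistent probability of responsive spines before renormalisation.
#' @return A list with `presence` (tibble: spine_id, session, present) and
#'   `categories` (tibble: spine_id, category).
#' @export
generate_presence_schedules <- function(n_spines, n_sessions,
                                        category_probs = c(persistent = 0.197,
                                                           transient = 0.456,
                                                           formed = 0.169,
                                                           eliminated = 0.178),
                                        seed = 1L,
                                        responsive = NULL,
                                        persistence_odds_multiplier = 1) {
  check_number(n_spines, "n_spines", lower = 1, integer = TRUE)
  check_number(n_sessions, "n_sessions", lower = 2, integer = TRUE)
  if (length(category_probs) != 4L || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-8) {
    abort("`category_probs` must be 4 non-negative probabilities summing to 1.")
  }
  cats <- c("persistent", "transient", "formed", "eliminated")
  category_probs <- setNames(as.numeric(category_probs), cats)
  if (is.null(responsive)) responsive <- rep(FALSE, n_spines)
  stopifnot(length(responsive) == n_spines)

  # Enumerate every non-empty schedule and pool them by category, so any
  # drawn schedule round-trips exactly through classify_survival().
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_sessions)))
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  pool_cat <- apply(grid, 1L, classify_survival)
  pools <- lapply(cats, function(cc) which(pool_cat == cc))
  names(pools) <- cats

  with_seed(seed, {
    schedule <- matrix(FALSE, n_spines, n_sessions)
    category <- character(n_spines)
    for (i in seq_len(n_spines)) {
      p <- category_probs
      p[vapply(pools, length, integer(1)) == 0L] <- 0 # e.g. no transient at 2 sessions
      if (sum(p) == 0) abort("no realisable category has positive probability")
      if (responsive[i]) {
        p["persistent"] <- p["persistent"] * persistence_odds_multiplier
      }
      p <- p / sum(p)
      category[i] <- sample(cats, 1L, prob = p)
      pick <- pools[[category[i]]]
      schedule[i, ] <- grid[pick[sample.int(length(pick), 1L)], ]
    }
    spine_id <- sprintf("spine_%03d", seq_len(n_spines))
    list(
      presence = tibble::tibble(
        spine_id = rep(spine_id, each = n_sessions),
        session = rep(seq_len(n_sessions), n_spines),
        present = as.vector(t(schedule))
      ),
      categories = tibble::tibble(spine_id = spine_id, category = category)
    )
  })
}

# Skeleton (path graph per dendrite, gentle 2D wiggle) plus spine
# attachments; connected spines cluster around a random centre.
generate_skeleton <- function(spines, cluster_sd_um, seed, spacing_um = 1.5) {
  with_seed(seed, {
    dendrites <- sort(unique(spines$dendrite_id))
    nodes <- list(); edges <- list()
    attach_node <- integer(nrow(spines))
    offset <- 0L
    for (d in dendrites) {
      idx <- which(spines$dendrite_id == d)
      n_nodes <- max(20L, 2L * length(idx))
      step <- spacing_um + abs(rnorm(n_nodes - 1L, 0, 0.1))
      ang <- cumsum(rnorm(n_nodes - 1L, 0, 0.15))
      x <- c(0, cumsum(step * cos(ang)))
      y <- c(0, cumsum(step * sin(ang))) + 100 * (match(d, dendrites) - 1L)
      id <- offset + seq_len(n_nodes)
      nodes[[length(nodes) + 1L]] <- tibble::tibble(
        node = id, dendrite_id = d, x = x, y = y)
      seg_len <- sqrt(diff(x)^2 + diff(y)^2)
      edges[[length(edges) + 1L]] <- tibble::tibble(
        node_a = id[-n_nodes], node_b = id[-1L], length_um = seg_len)
      # arc-length position of each node along this dendrite
      arc <- c(0, cumsum(seg_len))
      centre <- runif(1L, min(arc), max(arc))
      for (i in idx) {
        pos <- if (spines$connected[i]) {
          rnorm(1L, centre, cluster_sd_um)
        } else {
          runif(1L, min(arc), max(arc))
        }
        attach_node[i] <- id[which.min(abs(arc - pos))]
      }
      offset <- offset + n_nodes
    }
    dendrite_skeleton(
      nodes = dplyr::bind_rows(nodes),
      edges = dplyr::bind_rows(edges),
      attachments = tibble::tibble(spine_id = spines$spine_id, node = attach_node)
    )
  })
}

#' Generate a full synthetic spine-imaging experiment
#'
#' Simulates raw fluorescence traces for dendrite, spine and background ROIs
#' over multiple sessions of optogenetic stimulation trials, together with
#' the ground truth that produced them. Dendrite traces carry rare
#' suprathreshold back-propagating events plus a small bleed-through of
#' spine signals; every spine trace contains the dendritic component scaled
#' by a coupling coefficient, and connected spines additionally receive
#' per-pulse Bernoulli release successes convolved with a
#' difference-of-exponentials indicator kernel. Motion epochs, additive
#' noise and mild bleaching complete the traces. All randomness derives
#' from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @return A list of class `spine_experiment` with elements `config`,
#'   `sessions` (per session: `onset_frames` (0-based), `motion` flags, raw
#'   fluorescence matrix `F` with one column per ROI, `roi_info`),
#'   `ground_truth` (class `spine_ground_truth`), `skeleton`
#'   (class `dendrite_skeleton`) and `images` (per-spine [roi_image()]s,
#'   if requested).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  fs <- cfg$frame_rate
  n_sp <- cfg$n_spines

  spine_id <- sprintf("spine_%03d", seq_len(n_sp))
  dendrite_id <- sprintf("dendrite_%02d", (seq_len(n_sp) - 1L) %% cfg$n_dendrites + 1L)
  dend_ids <- sprintf("dendrite_%02d", seq_len(cfg$n_dendrites))

  gt_seed <- derive_seed(cfg$seed, 1L)
  spines <- with_seed(gt_seed, {
    connected <- runif(n_sp) < cfg$fraction_connected
    true_volume <- rlnorm(n_sp, cfg$volume_meanlog, cfg$volume_sdlog)
    amp <- pmax(cfg$amplitude_floor,
                cfg$amplitude_slope * true_volume + rnorm(n_sp, 0, cfg$amplitude_noise_sd))
    tibble::tibble(
      spine_id = spine_id,
      dendrite_id = dendrite_id,
      connected = connected,
      release_probability = ifelse(connected, cfg$release_probability, 0),
      epscat_amplitude = ifelse(connected, amp, 0),
      true_volume = true_volume,
      f0 = 80 * runif(n_sp, 0.8, 1.2)
    )
  })

  sched <- generate_presence_schedules(
    n_spines = n_sp, n_sessions = cfg$n_sessions,
    category_probs = cfg$category_probs,
    seed = derive_seed(cfg$seed, 2L),
    responsive = spines$connected,
    persistence_odds_multiplier = cfg$persistence_odds_multiplier
  )

  skeleton <- generate_skeleton(spines, cfg$cluster_sd_um,
                                seed = derive_seed(cfg$seed, 3L))
  spines$node <- skeleton$attachments$node[match(spine_id, skeleton$attachments$spine_id)]

  iti_frames <- round(cfg$inter_trial_interval * fs)
  lead <- 2L * round(fs)
  n_frames <- lead + cfg$n_trials_per_session * iti_frames + iti_frames
  onsets <- lead + (seq_len(cfg$n_trials_per_session) - 1L) * iti_frames
  pulse_off <- round((seq_len(cfg$pulses_per_trial) - 1L) * fs / cfg$pulse_rate)
  kernel <- epscat_kernel(fs, cfg$rise_tau, cfg$decay_tau)
  bleach <- 1 - cfg$bleach_fraction * (seq_len(n_frames) - 1L) / (n_frames - 1L)

  roi_info <- tibble::tibble(
    roi_id = c(spine_id, dend_ids, "background"),
    roi_kind = c(rep("spine", n_sp), rep("dendrite", cfg$n_dendrites), "background"),
    dendrite_id = c(dendrite_id, dend_ids, NA_character_)
  )
  f0_roi <- c(spines$f0, rep(cfg$baseline_f, cfg$n_dendrites), 20)

  sessions <- vector("list", cfg$n_sessions)
  events <- list(); releases <- list()
  conn_idx <- which(spines$connected)
  for (s in seq_len(cfg$n_sessions)) {
    sessions[[s]] <- with_seed(derive_seed(cfg$seed, 100L + s), {
      # motion epochs: Poisson arrivals, exponential durations
      n_min <- n_frames / fs / 60
      motion <- rep(FALSE, n_frames)
      n_ep <- rpois(1L, cfg$motion_epoch_rate * n_min)
      if (n_ep > 0) {
        starts <- sort(sample.int(n_frames, n_ep, replace = TRUE))
        durs <- pmax(1L, round(rexp(n_ep, 1 / cfg$motion_epoch_duration) * fs))
        for (i in seq_len(n_ep)) {
          motion[starts[i]:min(n_frames, starts[i] + durs[i] - 1L)] <- TRUE
        }
      }

      # dendritic back-propagating events
      dend_sig <- matrix(0, n_frames, cfg$n_dendrites)
      ev <- matrix(runif(cfg$n_trials_per_session * cfg$n_dendrites) < cfg$dendritic_event_rate,
                   cfg$n_trials_per_session, cfg$n_dendrites)
      for (d in seq_len(cfg$n_dendrites)) {
        at <- onsets[ev[, d]]
        if (length(at)) {
          dend_sig[, d] <- add_kernel_events(dend_sig[, d], at,
                                             rep(cfg$dendritic_event_amplitude, length(at)),
                                             kernel)
        }
      }
      events[[length(events) + 1L]] <- tibble::tibble(
        session = s,
        dendrite_id = rep(dend_ids, each = cfg$n_trials_per_session),
        trial = rep(seq_len(cfg$n_trials_per_session), cfg$n_dendrites),
        dendritic_event = as.vector(ev)
      )

      # per-pulse release successes at connected spines
      own <- matrix(0, n_frames, n_sp)
      if (length(conn_idx)) {
        np <- cfg$n_trials_per_session * cfg$pulses_per_trial
        suc <- matrix(runif(np * length(conn_idx)) < cfg$release_probability,
                      np, length(conn_idx))
        pulse_frames <- rep(onsets, each = cfg$pulses_per_trial) +
          rep(pulse_off, cfg$n_trials_per_session)
        for (j in seq_along(conn_idx)) {
          at <- pulse_frames[suc[, j]]
          if (length(at)) {
            own[, conn_idx[j]] <- add_kernel_events(
              own[, conn_idx[j]], at,
              rep(spines$epscat_amplitude[conn_idx[j]], length(at)), kernel)
          }
        }
        releases[[length(releases) + 1L]] <- tibble::tibble(
          session = s,
          spine_id = rep(spines$spine_id[conn_idx], each = np),
          trial = rep(rep(seq_len(cfg$n_trials_per_session), each = cfg$pulses_per_trial),
                      length(conn_idx)),
          pulse = rep(rep(seq_len(cfg$pulses_per_trial), cfg$n_trials_per_session),
                      length(conn_idx)),
          success = as.vector(suc)
        )
      }

      dmat <- dend_sig[, match(dendrite_id, dend_ids), drop = FALSE]
      dff <- matrix(rnorm(n_frames * nrow(roi_info), 0, cfg$noise_sd),
                    n_frames, nrow(roi_info))
      if (any(motion)) {
        dff[motion, ] <- dff[motion, , drop = FALSE] +
          rnorm(sum(motion) * nrow(roi_info), 0, 5 * cfg$noise_sd)
      }
      dff[, seq_len(n_sp)] <- dff[, seq_len(n_sp)] +
        cfg$coupling_coefficient * dmat + own
      for (d in seq_len(cfg$n_dendrites)) {
        sp_on_d <- which(dendrite_id == dend_ids[d])
        bleed <- if (length(sp_on_d)) {
          rowMeans(own[, sp_on_d, drop = FALSE])
        } else 0
        dff[, n_sp + d] <- dff[, n_sp + d] + dend_sig[, d] + cfg$spine_bleed * bleed
      }
      fmat <- sweep(1 + dff, 2L, f0_roi, "*") * bleach
      colnames(fmat) <- roi_info$roi_id
      list(session = s, onset_frames = as.integer(onsets), motion = motion,
           F = fmat, roi_info = roi_info)
    })
  }

  images <- NULL
  if (isTRUE(cfg$generate_images)) {
    images <- lapply(seq_len(n_sp), function(i) {
      generate_volume_image(spines$true_volume[i],
                            seed = derive_seed(cfg$seed, 10000L + i))
    })
    names(images) <- spine_id
  }

  ground_truth <- structure(
    list(spines = spines,
         presence = sched$presence,
         categories = sched$categories,
         events = dplyr::bind_rows(events),
         releases = if (length(releases)) dplyr::bind_rows(releases) else
           tibble::tibble(session = integer(), spine_id = character(),
                          trial = integer(), pulse = integer(), success = logical())),
    class = "spine_ground_truth")

  structure(list(config = cfg, sessions = sessions, ground_truth = ground_truth,
                 skeleton = skeleton, images = images),
            class = "spine_experiment")
}

#' @export
print.spine_experiment <- function(x, ...) {
  cat("<spine_experiment>\n")
  print(x$config)
  invisible(x)
}

#' Tidy accessors for a synthetic experiment
#'
#' `experiment_traces()` returns the per-frame fluorescence of every ROI in
#' long format; `experiment_trials()` returns the trial-onset table. Both
#' match the CSV schema written by [write_experiment()].
#'
#' @param experiment A `spine_experiment`.
#' @param sessions Optional integer vector restricting sessions.
#' @return A tibble.
#' @export
experiment_traces <- function(experiment, sessions = NULL) {
  stopifnot(inherits(experiment, "spine_experiment"))
  keep <- sessions %||% seq_along(experiment$sessions)
  purrr::map_dfr(experiment$sessions[keep], function(ss) {
    nf <- nrow(ss$F)
    tibble::tibble(
      session = ss$session,
      roi_id = rep(ss$roi_info$roi_id, each = nf),
      roi_kind = rep(ss$roi_info$roi_kind, each = nf),
      frame = rep(seq_len(nf) - 1L, ncol(ss$F)),
      fluorescence = as.vector(ss$F),
      motion_flag = rep(ss$motion, ncol(ss$F))
    )
  })
}

#' @rdname experiment_traces
#' @export
experiment_trials <- function(experiment) {
  stopifnot(inherits(experiment, "spine_experiment"))
  purrr::map_dfr(experiment$sessions, function(ss) {
    tibble::tibble(session = ss$session,
                   trial = seq_along(ss$onset_frames),
                   onset_frame = ss$onset_frames)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic labelled volume image for one spine
#'
#' Draws a spine head (a disc whose area is proportional to the true volume)
#' next to a dendritic shaft, blurs both with a Gaussian point-spread
#' function, adds a constant background and Poisson-like shot noise, and
#' returns the intensity image together with spine / dendrite / background
#' ROI label masks — the input expected by [estimate_volume()].
#'
#' @param true_volume Ground-truth spine head volume (arbitrary units, >= 0).
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param background_level Constant background intensity.
#' @param seed Integer seed for the noise draw.
#' @param size Image side length in pixels.
#' @param noise Add Poisson-like noise? Disable for noise-free oracles.
#' @return A [roi_image()] whose `roles` table maps label 1 to the spine ROI
#'   ("spine_001"), 2 to the dendrite ROI and 3 to the background ROI.
#' @export
generate_volume_image <- function(true_volume, psf_sigma = 1.5,
                                  background_level = 10, seed = 1L,
                                  size = 48L, noise = TRUE) {
  check_number(true_volume, "true_volume", lower = 0)
  check_number(psf_sigma, "psf_sigma", lower = 1e-9)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)

  img <- matrix(0, size, size)
  shaft <- rows >= size - 12L & rows <= size - 8L
  img[shaft] <- 100
  spine_centre <- c(round(size * 0.4), round(size / 2))
  r_spine <- sqrt(8 * true_volume / pi)
  if (true_volume > 0) {
    disc <- (rows - spine_centre[1])^2 + (cols - spine_centre[2])^2 <= r_spine^2
    if (!any(disc)) { # sub-pixel spine: deposit the equivalent flux in one pixel
      img[spine_centre[1], spine_centre[2]] <- 100 * 8 * true_volume
    } else {
      img[disc] <- 100
    }
  }
  img <- gaussian_blur(img, psf_sigma) + background_level
  if (noise) {
    img <- with_seed(seed, matrix(rpois(size * size, pmax(img, 0)), size, size))
  }

  labels <- matrix(0L, size, size)
  spine_roi <- (rows - spine_centre[1])^2 + (cols - spine_centre[2])^2 <= (r_spine + 4)^2
  labels[spine_roi] <- 1L
  labels[shaft] <- 2L
  labels[rows <= 8L & cols <= 8L] <- 3L
  roi_image(intensity = img, labels = labels,
            roles = tibble::tibble(label = 1:3,
                                   roi_id = c("spine_001", "dendrite_01", "background"),
                                   roi_kind = c("spine", "dendrite", "background")))
}
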