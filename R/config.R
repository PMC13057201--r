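#' Configuration of a synthetic spine-imaging experiment
#'
#' Bundles the stimulation protocol and the generative parameters used by
#' [generate_experiment()]. The protocol defaults mirror a chronic
#' subthreshold mapping experiment: five imaging sessions four days apart,
#' each with 40 optogenetic stimulation trials of 3 light pulses (10 ms at
#' 10 Hz) spaced by 5 s, imaged at 30 Hz. Parameters the underlying study
#' does not pin down (indicator kinetics, noise, coupling) are engineering
#' choices exposed here; see the methods vignette for the rationale.
#'
#' @param n_sessions Number of imaging sessions (>= 2).
#' @param n_trials_per_session Stimulation trials per session.
#' @param frame_rate Imaging frame rate in Hz.
#' @param pulses_per_trial Light pulses per trial.
#' @param pulse_duration Pulse duration in seconds.
#' @param pulse_rate Pulse rate within the train, Hz.
#' @param inter_trial_interval Trial spacing in seconds.
#' @param n_spines Number of spines simulated.
#' @param n_dendrites Number of dendritic segments the spines are spread over.
#' @param fraction_connected Probability that a spine receives functional
#'   input from the stimulated presynaptic population.
#' @param release_probability Per-pulse vesicle release probability at
#'   connected synapses.
#' @param dendritic_event_rate Per-trial probability of a suprathreshold
#'   back-propagating dendritic calcium event.
#' @param noise_sd Additive per-frame noise, in dF/F units.
#' @param rise_tau,decay_tau Indicator kernel time constants in seconds
#'   (difference of exponentials).
#' @param motion_epoch_rate Motion epochs per minute (Poisson arrivals).
#' @param motion_epoch_duration Mean epoch duration in seconds (exponential).
#' @param coupling_coefficient Fraction of the dendritic dF/F signal that
#'   bleeds into each spine trace.
#' @param spine_bleed Fraction of the average spine-evoked signal that bleeds
#'   back into the dendrite trace.
#' @param dendritic_event_amplitude Peak dF/F of a dendritic event.
#' @param amplitude_slope,amplitude_noise_sd,amplitude_floor EPSCaT peak
#'   amplitude of a connected spine is
#'   `max(amplitude_floor, amplitude_slope * volume + N(0, amplitude_noise_sd))`,
#'   a weak positive volume-amplitude coupling.
#' @param volume_meanlog,volume_sdlog Log-normal parameters of true spine
#'   head volumes (arbitrary units).
#' @param category_probs Probabilities of the four longitudinal categories
#'   (persistent, transient, formed, eliminated) used for presence schedules.
#' @param persistence_odds_multiplier Odds multiplier applied to the
#'   persistent category for connected spines (> 1 biases connected spines
#'   towards persistence).
#' @param cluster_sd_um Spatial spread (um, along the dendrite) of connected
#'   spines around a cluster centre; unconnected spines attach uniformly.
#' @param baseline_f Mean raw-fluorescence baseline of a dendrite ROI.
#' @param bleach_fraction Fractional fluorescence lost to bleaching over one
#'   session (linear in time).
#' @param generate_images Render a labelled volume image per spine?
#' @param seed Master seed; every random draw derives from it.
#'
#' @return A validated list of class `experiment_config`.
#' @seealso [generate_experiment()], [trial_window()]
#' @export
experiment_config <- function(n_sessions = 5,
                              n_trials_per_session = 40,
                              frame_rate = 30,
                              pulses_per_trial = 3,
                              pulse_duration = 0.010,
                              pulse_rate = 10,
                              inter_trial_interval = 5,
                              n_spines = 55,
                              n_dendrites = 1,
                              fraction_connected = 0.19,
                              release_probability = 0.3,
                              dendritic_event_rate = 0.059,
                              noise_sd = 0.1,
                              rise_tau = 0.05,
                              decay_tau = 0.5,
                              motion_epoch_rate = 4,
                              motion_epoch_duration = 1.5,
                              coupling_coefficient = 0.8,
                              spine_bleed = 0.05,
                              dendritic_event_amplitude = 1.5,
                              amplitude_slope = 0.5,
                              amplitude_noise_sd = 0.8,
                              amplitude_floor = 0.1,
                              volume_meanlog = 0,
                              volume_sdlog = 0.5,
                              category_probs = c(persistent = 0.197,
                                                 transient = 0.456,
                                                 formed = 0.169,
                                                 eliminated = 0.178),
                              persistence_odds_multiplier = 3,
                              cluster_sd_um = 10,
                              baseline_f = 100,
                              bleach_fraction = 0.03,
                              generate_images = TRUE,
                              seed = 1L) {
  check_number(n_sessions, "n_sessions", lower = 2, integer = TRUE)
  check_number(n_trials_per_session, "n_trials_per_session", lower = 1, integer = TRUE)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(pulses_per_trial, "pulses_per_trial", lower = 1, integer = TRUE)
  check_number(pulse_duration, "pulse_duration", lower = 1e-9)
  check_number(pulse_rate, "pulse_rate", lower = 1e-9)
  check_number(inter_trial_interval, "inter_trial_interval", lower = 1e-9)
  check_number(n_spines, "n_spines", lower = 1, integer = TRUE)
  check_number(n_dendrites, "n_dendrites", lower = 1, integer = TRUE)
  check_probability(fraction_connected, "fraction_connected")
  check_probability(release_probability, "release_probability")
  check_probability(dendritic_event_rate, "dendritic_event_rate")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(rise_tau, "rise_tau", lower = 1e-9)
  check_number(decay_tau, "decay_tau", lower = 1e-9)
  check_number(motion_epoch_rate, "motion_epoch_rate", lower = 0)
  check_number(motion_epoch_duration, "motion_epoch_duration", lower = 1e-9)
  check_probability(coupling_coefficient, "coupling_coefficient")
  check_number(seed, "seed", integer = TRUE)
  if (length(category_probs) != 4L || any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-8) {
    abort("`category_probs` must be 4 non-negative probabilities summing to 1.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  %d sessions x %d trials, %d x %.0f ms pulses at %g Hz, ITI %g s, %g Hz sampling\n",
              x$n_sessions, x$n_trials_per_session, x$pulses_per_trial,
              1000 * x$pulse_duration, x$pulse_rate, x$inter_trial_interval,
              x$frame_rate))
  cat(sprintf("  %d spines on %d dendrite(s); fraction connected %.2f, release p %.2f, seed %d\n",
              x$n_spines, x$n_dendrites, x$fraction_connected,
              x$release_probability, x$seed))
  invisible(x)
}

#' Per-trial analysis window
#'
#' Frame counts delimiting the analysis window around each stimulation
#' onset: a 1 s stable baseline before onset, the stimulation window (pulse
#' train plus one frame; 7 frames at 30 Hz for a 0.21 s train), and the
#' post-stimulus frames searched when measuring response amplitude.
#'
#' @param baseline_frames Baseline frames before onset (default 30 = 1 s at 30 Hz).
#' @param stim_frames Frames of the stimulation window.
#' @param response_frames Post-stimulation frames kept for amplitude search
#'   (default 15 = 0.5 s at 30 Hz).
#' @return A list of class `trial_window`.
#' @export
trial_window <- function(baseline_frames = 30, stim_frames = 7, response_frames = 15) {
  check_number(baseline_frames, "baseline_frames", lower = 1, integer = TRUE)
  check_number(stim_frames, "stim_frames", lower = 1, integer = TRUE)
  check_number(response_frames, "response_frames", lower = 1, integer = TRUE)
  structure(list(baseline_frames = as.integer(baseline_frames),
                 stim_frames = as.integer(stim_frames),
                 response_frames = as.integer(response_frames)),
            class = "trial_window")
}

window_length <- function(window) {
  window$baseline_frames + window$stim_frames + window$response_frames
}

# Default window implied by a config: 1 s baseline, pulse train + 1 frame,
# 0.5 s of post-train decay.
default_window <- function(config) {
  fs <- config$frame_rate
  train <- (config$pulses_per_trial - 1) / config$pulse_rate + config$pulse_duration
  trial_window(baseline_frames = round(fs),
               stim_frames = floor(train * fs) + 1L,
               response_frames = round(0.5 * fs))
}
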