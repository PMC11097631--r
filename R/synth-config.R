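# Configuration objects for the synthetic-data generators.

#' Configuration for the synthetic two-photon dataset
#'
#' Defaults describe the recording world the analysis is built for: an
#' 820 um x 820 um field of view imaged at 29.76 frames/s, a tonotopic
#' gradient spanning the 4-64 kHz (4 octave) axis across the field, local
#' best-frequency scatter on top of the gradient, a mixture of single-peak,
#' double-peak and irregular (untuned) neurons, and 10 stimulus repetitions.
#'
#' @param n_neurons number of neurons
#' @param fov_extent side of the square field of view (um)
#' @param gradient_axis unit vector of the tonotopic gradient in the imaging
#'   plane (normalized internally)
#' @param gradient_rate gradient steepness, octaves per um; the default runs
#'   the full 4-octave axis across one field
#' @param scatter_sd sd of local best-frequency jitter around the gradient
#'   (octaves)
#' @param class_fractions named proportions over `single`, `double`,
#'   `irregular`; must sum to 1
#' @param response_gain peak tuning amplitude, spike-probability units
#' @param trial_noise_sd sd of i.i.d. trial noise, same units
#' @param n_repetitions stimulus repetitions
#' @param frame_rate imaging frame rate (Hz)
#' @param n_ensembles latent sound ensembles (used by the two-session
#'   generator)
#' @param drift_fraction fraction of neurons whose ensemble loading is
#'   redrawn in session 2
#' @param rng_seed integer seed; every generator is deterministic given it
#' @param neuropil_baseline,neuropil_noise_sd,neuropil_drift_amp neuropil
#'   trace model (a.u.): constant baseline + slow sinusoidal drift + white
#'   noise
#' @param trace_noise_sd white noise added to the raw ROI trace (a.u.)
#' @param transient_amp peak amplitude of one calcium transient (a.u.); the
#'   defaults plant a PSNR of ~41 dB (peak ~285 over a neuropil sd of
#'   ~2.4), comfortably above the 36 dB retention threshold
#' @param transient_tau decay time constant of the transient kernel (s)
#' @param run_prob probability that any given second of the session is part
#'   of a running bout
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_neurons = 200,
                         fov_extent = 820,
                         gradient_axis = c(1, 0),
                         gradient_rate = 4 / 820,
                         scatter_sd = 0.5,
                         class_fractions = c(single = 0.6, double = 0.15,
                                             irregular = 0.25),
                         response_gain = 1,
                         trial_noise_sd = 0.25,
                         n_repetitions = 10,
                         frame_rate = 29.76,
                         n_ensembles = 3,
                         drift_fraction = 0,
                         rng_seed = 1L,
                         neuropil_baseline = 50,
                         neuropil_noise_sd = 2,
                         neuropil_drift_amp = 2,
                         trace_noise_sd = 1,
                         transient_amp = 300,
                         transient_tau = 0.5,
                         run_prob = 0) {
  cfg <- list(n_neurons = n_neurons, fov_extent = fov_extent,
              gradient_axis = gradient_axis, gradient_rate = gradient_rate,
              scatter_sd = scatter_sd, class_fractions = class_fractions,
              response_gain = response_gain, trial_noise_sd = trial_noise_sd,
              n_repetitions = n_repetitions, frame_rate = frame_rate,
              n_ensembles = n_ensembles, drift_fraction = drift_fraction,
              rng_seed = rng_seed, neuropil_baseline = neuropil_baseline,
              neuropil_noise_sd = neuropil_noise_sd,
              neuropil_drift_amp = neuropil_drift_amp,
              trace_noise_sd = trace_noise_sd,
              transient_amp = transient_amp, transient_tau = transient_tau,
              run_prob = run_prob)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  num <- cfg[setdiff(names(cfg), "class_fractions")]
  bad <- names(num)[!vapply(num, function(v) all(is.finite(v)), logical(1))]
  if (length(bad))
    stop("non-finite config values: ", paste(bad, collapse = ", "))
  if (cfg$n_neurons < 1 || cfg$n_neurons != round(cfg$n_neurons))
    stop("'n_neurons' must be a positive integer")
  cf <- cfg$class_fractions
  if (!all(c("single", "double", "irregular") %in% names(cf)))
    stop("class_fractions must be named single/double/irregular")
  if (!all(is.finite(cf)) || any(cf < 0) || abs(sum(cf) - 1) > 1e-8)
    stop("class_fractions must be nonnegative and sum to 1")
  sds <- c(cfg$scatter_sd, cfg$trial_noise_sd, cfg$neuropil_noise_sd,
           cfg$trace_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$drift_fraction < 0 || cfg$drift_fraction > 1)
    stop("'drift_fraction' must lie in [0, 1]")
  if (cfg$frame_rate <= 0) stop("'frame_rate' must be > 0")
  if (sqrt(sum(cfg$gradient_axis^2)) == 0)
    stop("'gradient_axis' must be a nonzero vector")
  invisible(cfg)
}

#' Configuration for the synthetic widefield movie
#'
#' The planted map is radial: a low-frequency hub from which best frequency
#' rises with distance up to a crest (the planted tonotopic reversal ring)
#' and falls beyond it. A silent margin of non-responsive pixels frames the
#' "end of the auditory cortex". Five pure tones (4-64 kHz, one per octave),
#' 500 ms tone / 5 s pause, 16 repetitions at 10 Hz, as in the widefield
#' paradigm the analysis targets.
#'
#' @param width,height frame size in pixels (the native analysis resolution
#'   is 256; note a 256 x 256 movie occupies ~2.3 GB as doubles)
#' @param hub hub center (x, y) in pixels; default slightly off-center
#' @param crest_radius radius of the planted reversal ring (px)
#' @param margin width of the planted non-responsive border (px)
#' @param tone_khz widefield tone set
#' @param n_rep repetitions per tone
#' @param frame_rate Hz
#' @param tone_s,pause_s,lead_in_s timing (s)
#' @param baseline mean fluorescence (a.u.)
#' @param amp peak evoked amplitude at a perfectly matched pixel (a.u.)
#' @param tuning_width_oct Gaussian width of pixel tuning (octaves)
#' @param noise_sd white noise sd (a.u.)
#' @param drift_amp amplitude of the slow multiplicative baseline drift
#'   (fraction of baseline)
#' @param rng_seed integer seed
#' @return object of class `widefield_config`
#' @export
widefield_config <- function(width = 256, height = 256,
                             hub = NULL, crest_radius = NULL, margin = 12,
                             tone_khz = c(4, 8, 16, 32, 64), n_rep = 16,
                             frame_rate = 10, tone_s = 0.5, pause_s = 5,
                             lead_in_s = 5, baseline = 100, amp = 30,
                             tuning_width_oct = 0.8, noise_sd = 0.5,
                             drift_amp = 0.02, rng_seed = 1L) {
  if (width < 64 || height < 64)
    stop("stack dimensions must be at least 64 x 64")
  hub <- hub %||% c(round(width * 0.45), round(height * 0.5))
  crest_radius <- crest_radius %||% round(0.3 * min(width, height))
  if (hub[1] < 1 || hub[1] > width || hub[2] < 1 || hub[2] > height)
    stop("hub placed outside frame")
  cfg <- list(width = width, height = height, hub = hub,
              crest_radius = crest_radius, margin = margin,
              tone_khz = tone_khz, n_rep = n_rep, frame_rate = frame_rate,
              tone_s = tone_s, pause_s = pause_s, lead_in_s = lead_in_s,
              baseline = baseline, amp = amp,
              tuning_width_oct = tuning_width_oct, noise_sd = noise_sd,
              drift_amp = drift_amp, rng_seed = rng_seed)
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (!all(is.finite(num))) stop("non-finite widefield config values")
  if (noise_sd < 0 || baseline <= 0) stop("invalid noise_sd/baseline")
  structure(cfg, class = "widefield_config")
}

#' Configuration for the two-session ensemble generator
#'
#' K latent ensembles; each assigned sound belongs to one ensemble, plus
#' optional unassigned sounds that drive no ensemble. Neuron loadings define
#' the cell vectors; session 2 redraws the loadings of a `drift_fraction` of
#' neurons (representational drift).
#'
#' @param n_sounds total sounds
#' @param n_ensembles K latent ensembles (error if > n_sounds)
#' @param n_unassigned sounds assigned to no ensemble
#' @param n_neurons neurons per FOV
#' @param n_rep repetitions per sound
#' @param noise_sd trial noise sd (response units; loadings are U(0,1))
#' @param drift_fraction fraction of neurons redrawn in session 2
#' @param rng_seed integer seed
#' @return object of class `ensemble_config`
#' @export
ensemble_config <- function(n_sounds = 15, n_ensembles = 3, n_unassigned = 0,
                            n_neurons = 40, n_rep = 10, noise_sd = 0.05,
                            drift_fraction = 0, rng_seed = 1L) {
  if (n_ensembles > n_sounds)
    stop("more ensembles than sounds")
  if (n_unassigned >= n_sounds)
    stop("all sounds unassigned")
  if (drift_fraction < 0 || drift_fraction > 1)
    stop("'drift_fraction' must lie in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(n_sounds = n_sounds, n_ensembles = n_ensembles,
                 n_unassigned = n_unassigned, n_neurons = n_neurons,
                 n_rep = n_rep, noise_sd = noise_sd,
                 drift_fraction = drift_fraction, rng_seed = rng_seed),
            class = "ensemble_config")
}
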