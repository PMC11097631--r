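# Synthetic two-photon population: planted tonotopy, tuning classes,
# trial responses, and full traces.

#' Generate a synthetic neuron population with planted ground truth
#'
#' Positions are uniform in the field of view. The true best frequency (BF)
#' of each neuron is the projection of its position onto the tonotopic
#' gradient axis (octave axis centred at 16 kHz mid-field) plus Gaussian
#' scatter, clipped to the 4-64 kHz axis. Tuning classes are drawn from
#' `class_fractions`; single- and double-peak neurons receive Gaussian tuning
#' parameters (amplitude A, centre B, width C, offset D on the octave axis),
#' irregular neurons have zero tuning amplitude.
#'
#' @param config a [synth_config()] object
#' @return list with `neurons` (data.frame of id/position/FOV stubs) and
#'   `truth` (one row per neuron: class, bf_khz, bf_oct, A1, B1, C1, A2, B2,
#'   C2, D, ensemble loading seed)
#' @export
generate_population <- function(config) {
  validate_synth_config(config)
  with_seed(config$rng_seed, {
    n <- config$n_neurons
    ax <- config$gradient_axis / sqrt(sum(config$gradient_axis^2))
    x <- stats::runif(n, 0, config$fov_extent)
    y <- stats::runif(n, 0, config$fov_extent)
    proj <- (x - config$fov_extent / 2) * ax[1] +
      (y - config$fov_extent / 2) * ax[2]
    bf_oct <- clamp(2 + proj * config$gradient_rate +
                      stats::rnorm(n, 0, config$scatter_sd), 0, 4)
    cls <- sample(names(config$class_fractions), n, replace = TRUE,
                  prob = config$class_fractions)
    g <- config$response_gain
    A1 <- ifelse(cls == "irregular", 0, g * stats::runif(n, 0.8, 1.2))
    B1 <- bf_oct
    C1 <- stats::runif(n, 0.3, 0.8)
    # second peak: placed >= 1.5 oct away, folded to stay on the axis,
    # smaller than the first so the planted BF remains B1
    sep <- stats::runif(n, 1.5, 2.5)
    up <- B1 + sep <= 4 & (B1 - sep < 0 | stats::runif(n) < 0.5)
    B2 <- ifelse(up, pmin(B1 + sep, 4), pmax(B1 - sep, 0))
    A2 <- ifelse(cls == "double", A1 * stats::runif(n, 0.5, 0.9), 0)
    C2 <- stats::runif(n, 0.3, 0.8)
    D <- 0.05 * g
    truth <- data.frame(
      neuron_id = sprintf("n%04d", seq_len(n)),
      x = x, y = y, fov_id = "FOV1", depth = 200,
      class = cls, bf_oct = bf_oct, bf_khz = oct_to_khz(bf_oct),
      A1 = A1, B1 = B1, C1 = C1,
      A2 = A2, B2 = ifelse(cls == "double", B2, NA_real_),
      C2 = ifelse(cls == "double", C2, NA_real_), D = D,
      stringsAsFactors = FALSE)
    neurons <- truth[, c("neuron_id", "x", "y", "fov_id", "depth")]
    list(neurons = neurons, truth = truth, config = config)
  })
}

# planted mean response of one neuron to a tone at x octaves (no SPL gain)
planted_tuning <- function(truth_row, x_oct) {
  v <- truth_row$A1 * exp(-((x_oct - truth_row$B1) / truth_row$C1)^2)
  if (!is.na(truth_row$B2) && truth_row$A2 > 0)
    v <- v + truth_row$A2 * exp(-((x_oct - truth_row$B2) / truth_row$C2)^2)
  v
}

#' Generate per-trial mean responses for the pure-tone grid
#'
#' The mean post-onset response of neuron i to tone (f, SPL) on repetition r
#' is its planted Gaussian tuning evaluated at the tone's octave position,
#' multiplied by a monotone saturating SPL gain, plus the offset D, plus
#' i.i.d. Gaussian trial noise, rectified at zero (deconvolved spike
#' probabilities are nonnegative).
#'
#' @param pop result of [generate_population()]
#' @param protocol a [pt_protocol()] covering the 17 x 5 grid
#' @param config the same [synth_config()]
#' @return data.frame: neuron_id, sound_id, freq_khz, spl_db, rep, response
#' @export
generate_trial_responses <- function(pop, protocol, config = pop$config) {
  ev <- protocol$events
  if (any(ev$class == "PT" & (ev$freq_khz < 4 - 1e-9 |
                              ev$freq_khz > 64 + 1e-9)))
    stop("tone frequency outside the planted 4-64 kHz axis")
  truth <- pop$truth
  x_oct <- khz_to_oct(ev$freq_khz)
  gain <- spl_gain(ev$spl_db)
  with_seed(config$rng_seed + 1L, {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      mu <- planted_tuning(tr, x_oct) * gain + tr$D
      resp <- pmax(mu + stats::rnorm(length(mu), 0, config$trial_noise_sd), 0)
      data.frame(neuron_id = tr$neuron_id, sound_id = ev$sound_id,
                 freq_khz = ev$freq_khz, spl_db = ev$spl_db, rep = ev$rep,
                 response = resp, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate full synthetic traces (raw, neuropil, spikes) and a speed trace
#'
#' Per neuron: the neuropil trace is a constant baseline plus a slow
#' sinusoidal drift plus white noise; stimulus-locked calcium transients
#' (single-exponential decay kernel, tau = `transient_tau`) are scaled by the
#' neuron's planted tuning; raw = 0.7 * neuropil + transients + white noise.
#' The spike-probability trace carries the (noise-free) transient onsets.
#' The speed trace alternates rest and running bouts with per-second run
#' probability `run_prob`.
#'
#' @param pop result of [generate_population()]
#' @param protocol a [pt_protocol()]
#' @param config the same [synth_config()]
#' @return list with `recordings` (list of [neuron_recording()]) and `speed`
#'   (cm/s per frame)
#' @export
generate_traces <- function(pop, protocol, config = pop$config) {
  truth <- pop$truth
  ev <- protocol$events
  n_frames <- protocol$n_frames
  fr <- protocol$frame_rate
  decay <- exp(-1 / (config$transient_tau * fr))
  x_oct <- khz_to_oct(ev$freq_khz)
  gain <- spl_gain(ev$spl_db)
  with_seed(config$rng_seed + 2L, {
    tt <- seq_len(n_frames) / fr
    recs <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      phase <- stats::runif(1, 0, 2 * pi)
      neuropil <- config$neuropil_baseline +
        config$neuropil_drift_amp * sin(2 * pi * tt / max(tt) * 1.3 + phase) +
        stats::rnorm(n_frames, 0, config$neuropil_noise_sd)
      # stimulus-locked transient amplitudes, normalized to the neuron's peak
      tun <- planted_tuning(tr, x_oct) * gain + tr$D
      peak <- max(tun, config$response_gain * 1e-3)
      # trial-to-trial variability of the evoked transients
      tun_n <- pmax(tun + stats::rnorm(length(tun), 0,
                                       config$trial_noise_sd), 0)
      amps <- config$transient_amp * tun_n / peak
      impulses <- numeric(n_frames)
      ok <- ev$onset_frame >= 1 & ev$onset_frame <= n_frames
      impulses[ev$onset_frame[ok]] <- impulses[ev$onset_frame[ok]] + amps[ok]
      sig <- as.numeric(stats::filter(impulses, decay, method = "recursive"))
      raw <- 0.7 * neuropil + sig +
        stats::rnorm(n_frames, 0, config$trace_noise_sd)
      neuron_recording(raw = raw, neuropil = neuropil,
                       spikes = pmax(impulses, 0) / config$transient_amp,
                       position = c(tr$x, tr$y), fov_id = tr$fov_id,
                       depth = tr$depth, frame_rate = fr,
                       neuron_id = tr$neuron_id)
    })
    # running bouts: one state per second, expanded to frames
    n_sec <- ceiling(n_frames / fr)
    run <- stats::runif(n_sec) < config$run_prob
    spd <- ifelse(run, stats::runif(n_sec, 2, 10), 0)
    speed <- rep(spd, each = ceiling(fr))[seq_len(n_frames)]
    list(recordings = recs, speed = speed)
  })
}
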