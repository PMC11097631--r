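# Synthetic widefield movie with a planted radial tonotopic map.

#' Generate a synthetic widefield movie with planted ground truth
#'
#' The planted best-frequency field is radial: BF is lowest (4 kHz) at the
#' hub, rises linearly with distance to 64 kHz at `crest_radius` (the
#' planted tonotopic reversal ring) and falls again beyond it. The field is
#' snapped to the 5-tone set to define the per-pixel truth. A border of
#' `margin` pixels is non-responsive (the planted "end of auditory cortex").
#' Each tone presentation adds a ~1 s response time course whose amplitude
#' is a Gaussian (in octaves) of the mismatch between the pixel's BF and the
#' tone, on top of a slowly drifting multiplicative baseline plus white
#' noise.
#'
#' @param config a [widefield_config()]
#' @return object of class `widefield_movie`: list with `frames` (matrix,
#'   pixels x frames; pixel index runs down columns of the H x W image),
#'   `height`, `width`, `frame_rate`, `schedule` (data.frame tone_khz, rep,
#'   onset_frame, offset_frame), and `truth` (list: bf_oct / bf_khz matrices,
#'   `responsive` mask, `amp` pixel x tone matrix of planted evoked
#'   amplitudes, `hub`, `crest_radius`, `margin`)
#' @export
generate_widefield_movie <- function(config) {
  stopifnot(inherits(config, "widefield_config"))
  H <- config$height; W <- config$width
  npix <- H * W
  fr <- config$frame_rate
  tones_oct <- khz_to_oct(config$tone_khz)

  # planted BF field (octaves), radial around the hub
  px_x <- rep(seq_len(W), each = H)
  px_y <- rep(seq_len(H), times = W)
  d <- sqrt((px_x - config$hub[1])^2 + (px_y - config$hub[2])^2)
  up <- 4 * d / config$crest_radius
  down <- 4 - 3 * (d - config$crest_radius) / config$crest_radius
  bf_cont <- clamp(ifelse(d <= config$crest_radius, up, down), 0, 4)
  bf_snap <- tones_oct[apply(abs(outer(bf_cont, tones_oct, "-")), 1,
                             which.min)]
  responsive <- px_x > config$margin & px_x <= W - config$margin &
    px_y > config$margin & px_y <= H - config$margin
  # responses are driven by the snapped field, so each pixel has a unique
  # best tone (no amplitude ties at tone midpoints)
  amp <- outer(bf_snap, tones_oct,
               function(b, t) config$amp * exp(-((b - t) /
                                                 config$tuning_width_oct)^2))
  amp <- amp * responsive

  with_seed(config$rng_seed, {
    # schedule: randomized tone order within each repetition
    ord <- unlist(lapply(seq_len(config$n_rep), function(r)
      sample.int(length(config$tone_khz))))
    sched <- data.frame(
      tone_khz = config$tone_khz[ord],
      rep = rep(seq_len(config$n_rep), each = length(config$tone_khz)))
    step <- config$tone_s + config$pause_s
    onsets_s <- config$lead_in_s + (seq_len(nrow(sched)) - 1) * step
    sched$onset_frame <- floor(onsets_s * fr) + 1L
    sched$offset_frame <- floor((onsets_s + config$tone_s) * fr) + 1L
    n_frames <- ceiling((config$lead_in_s + nrow(sched) * step + 2) * fr)

    # slow multiplicative drift common to all pixels
    tt <- seq_len(n_frames) / n_frames
    g <- 1 + config$drift_amp * sin(2 * pi * 0.8 * tt + stats::runif(1, 0, 6))
    base_px <- config$baseline * (1 + 0.05 * stats::runif(npix, -1, 1))
    frames <- outer(base_px, g)
    kernel <- c(0.5, 0.9, 1, 1, 0.9, 0.6, 0.35, 0.2, 0.1, 0.05)
    tone_col <- match(sched$tone_khz, config$tone_khz)
    for (i in seq_len(nrow(sched))) {
      cols <- sched$onset_frame[i] + seq_along(kernel) - 1L
      cols <- cols[cols <= n_frames]
      frames[, cols] <- frames[, cols] +
        amp[, tone_col[i]] %o% kernel[seq_along(cols)]
    }
    if (config$noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames), 0, config$noise_sd)

    structure(list(frames = frames, height = H, width = W, frame_rate = fr,
                   schedule = sched,
                   truth = list(bf_oct = matrix(bf_snap, H, W),
                                bf_khz = matrix(oct_to_khz(bf_snap), H, W),
                                bf_cont_oct = matrix(bf_cont, H, W),
                                responsive = matrix(responsive, H, W),
                                amp = amp, hub = config$hub,
                                crest_radius = config$crest_radius,
                                margin = config$margin),
                   config = config),
              class = "widefield_movie")
  })
}

#' @export
print.widefield_movie <- function(x, ...) {
  cat("widefield_movie:", x$height, "x", x$width, "px,", ncol(x$frames),
      "frames @", x$frame_rate, "Hz,", nrow(x$schedule), "tone events\n")
  invisible(x)
}
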