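# Neuron-level preprocessing: PSNR filter, running exclusion, and the
# amplitude-rescaling control.

#' Peak signal-to-noise ratio of a neuron's trace
#'
#' PSNR = 20 * log10( max(F_raw - F_n) / sigma_n ), where F_raw is the ROI
#' trace, F_n the neuropil trace, and sigma_n the standard deviation of the
#' full neuropil trace. Adding a common constant to both traces leaves the
#' value unchanged.
#'
#' @param rec a [neuron_recording()]
#' @return PSNR in dB; `NA` (with a warning) when sigma_n = 0; `-Inf` when
#'   max(F_raw - F_n) <= 0 — both cases are excluded by [filter_neurons()]
#' @export
compute_psnr <- function(rec) {
  if (length(rec$raw) == 0) stop("traces must be nonempty")
  sigma_n <- stats::sd(rec$neuropil)
  if (!is.finite(sigma_n) || sigma_n == 0) {
    warning("degenerate neuropil trace (sd = 0) for neuron ",
            rec$neuron_id, "; PSNR undefined")
    return(NA_real_)
  }
  m <- max(rec$raw - rec$neuropil)
  if (m <= 0) return(-Inf)
  20 * log10(m / sigma_n)
}

#' Retain neurons whose PSNR is at or above threshold
#'
#' Neurons with PSNR strictly below 36 dB over the whole activity trace are
#' removed (a value of exactly 36 dB is retained). Degenerate neurons
#' (undefined PSNR) are removed.
#'
#' @param recs list of [neuron_recording()]
#' @param threshold retention threshold in dB (default 36)
#' @return the retained sublist, with attribute `psnr` (all computed values)
#' @export
filter_neurons <- function(recs, threshold = 36) {
  if (length(recs) == 0) {
    warning("empty recording list")
    return(recs)
  }
  psnr <- vapply(recs, compute_psnr, numeric(1))
  keep <- !is.na(psnr) & psnr >= threshold
  message(sum(keep), " of ", length(recs), " neurons retained at ",
          threshold, " dB")
  structure(recs[keep], psnr = psnr)
}

#' Mark stimulus repetitions contaminated by running
#'
#' A repetition of a sound is contaminated when the treadmill speed exceeds
#' `threshold` (strictly) during the sound-stimulation window. A field of
#' view is invalid when any analyzed sound retains fewer than `min_clean`
#' clean repetitions.
#'
#' @param protocol a `stimulus_protocol`
#' @param speed cm/s per frame, aligned to the recording frames
#' @param threshold cm/s (default 1; exactly 1 cm/s is retained)
#' @param min_clean minimum clean repetitions per sound (default 5)
#' @param window `"stim"` = onset..offset of the sound (default), or
#'   `"response"` = additionally `response_s` seconds after offset
#' @param response_s extension used when `window = "response"`
#' @return object of class `repetition_mask`: list with `mask` (data.frame
#'   sound_id, rep, clean), `clean_counts` per sound, and `fov_valid`
#' @export
exclude_running <- function(protocol, speed, threshold = 1, min_clean = 5,
                            window = c("stim", "response"), response_s = 0.4) {
  window <- match.arg(window)
  ev <- protocol$events
  if (max(ev$offset_frame) > length(speed))
    stop("speed trace shorter than the stimulus schedule (misaligned lengths)")
  ext <- if (window == "response")
    ceiling(response_s * protocol$frame_rate) else 0L
  contaminated <- vapply(seq_len(nrow(ev)), function(i) {
    fr <- ev$onset_frame[i]:min(ev$offset_frame[i] + ext, length(speed))
    any(speed[fr] > threshold)
  }, logical(1))
  mask <- data.frame(sound_id = ev$sound_id, rep = ev$rep,
                     clean = !contaminated, stringsAsFactors = FALSE)
  clean_counts <- tapply(mask$clean, mask$sound_id, sum)
  fov_valid <- all(clean_counts >= min_clean)
  structure(list(mask = mask, clean_counts = clean_counts,
                 fov_valid = fov_valid, threshold = threshold,
                 min_clean = min_clean),
            class = "repetition_mask")
}

# ---------------------------------------------------------------------------
# Orthogonal wavelet denoising (stand-in for MATLAB's "wdenoise" defaults).
# Periodized DWT with the sym4 filter; universal soft threshold on all
# detail levels, noise sd estimated from the finest detail by MAD.
# Reflection padding avoids the wrap-around discontinuity of periodization.

# sym4 orthonormal scaling filter (least-asymmetric Daubechies, 8 taps);
# coefficients sum to sqrt(2)
.sym4_lo <- c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545,  0.80373875180591614,
              0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783, 0.03222310060404270)

.wt_filters <- function() {
  h <- .sym4_lo
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror
  list(h = h, g = g)
}

# one analysis step: periodic convolution + dyadic downsampling
.dwt_step <- function(x) {
  f <- .wt_filters()
  N <- length(x)
  L <- length(f$h)
  idx <- outer(2 * (seq_len(N / 2) - 1), seq_len(L) - 1, "+") %% N + 1
  xm <- matrix(x[idx], nrow = N / 2)
  list(a = as.numeric(xm %*% f$h), d = as.numeric(xm %*% f$g))
}

# transpose (= inverse, by orthonormality) of .dwt_step
.idwt_step <- function(a, d) {
  f <- .wt_filters()
  N <- 2 * length(a)
  x <- numeric(N)
  for (k in seq_along(f$h)) {
    pos <- (2 * (seq_along(a) - 1) + (k - 1)) %% N + 1
    x[pos] <- x[pos] + f$h[k] * a + f$g[k] * d
  }
  x
}

#' Wavelet-denoise a trace (sym4, universal soft threshold)
#'
#' @param x numeric trace
#' @param level decomposition depth; default `max(floor(log2(n)) - 4, 1)`
#' @return the denoised (smooth) component, same length as `x`
#' @export
wavelet_denoise <- function(x, level = NULL) {
  n <- length(x)
  if (n < 16) return(x)
  # reflect to double length: continuous periodic extension
  xp <- c(x, rev(x))
  np <- length(xp)
  level <- level %||% max(floor(log2(n)) - 4, 1)
  level <- min(level, floor(log2(np)) - 3)
  # pad to a multiple of 2^level
  block <- 2^level
  pad <- (block - np %% block) %% block
  if (pad > 0) xp <- c(xp, rep(xp[np], pad))
  approx_v <- xp
  details <- vector("list", level)
  for (l in seq_len(level)) {
    st <- .dwt_step(approx_v)
    approx_v <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::mad(details[[1]], center = 0)
  thr <- sigma * sqrt(2 * log(length(xp)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  details <- lapply(details, soft)
  for (l in rev(seq_len(level)))
    approx_v <- .idwt_step(approx_v, details[[l]])
  approx_v[seq_len(n)]
}

#' Amplitude-rescaling control
#'
#' Wavelet-denoises the raw and neuropil traces, multiplies the denoised
#' (signal) component by `factor`, and adds the residual noise back
#' unchanged. Used to test whether a uniform reduction of calcium signal
#' amplitudes (to e.g. 86%) changes downstream results.
#'
#' @param rec a [neuron_recording()]
#' @param factor positive scale applied to the denoised component
#'   (default 0.86)
#' @return a new [neuron_recording()] with rescaled raw and neuropil traces
#' @export
rescale_traces <- function(rec, factor = 0.86) {
  if (!is.numeric(factor) || factor <= 0) stop("'factor' must be > 0")
  scale1 <- function(x) {
    den <- wavelet_denoise(x)
    factor * den + (x - den)
  }
  out <- rec
  out$raw <- scale1(rec$raw)
  out$neuropil <- scale1(rec$neuropil)
  out
}
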