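# Widefield pipeline: pixelwise dF/F, evoked detection, best-frequency
# maps, FOV merging, radial reversal detection, AC boundary, parcellation.

# Savitzky-Golay style sliding-polynomial baseline along rows of m
# (pixels x frames). Centered window of 2*half+1 frames, clipped at the
# movie edges (so at least half+1 frames always support the fit).
sliding_poly_baseline <- function(m, half, degree) {
  n_t <- ncol(m)
  if (n_t < 2 * half + 1)
    stop("movie shorter than the baseline window")
  x <- -half:half
  X <- outer(x, 0:degree, "^")
  hc <- as.numeric(X[half + 1, , drop = FALSE] %*%
                     solve(crossprod(X), t(X)))
  f0 <- matrix(NA_real_, nrow(m), n_t)
  chunk <- max(1L, floor(4e6 / n_t))
  for (i0 in seq(1, nrow(m), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(m))
    fi <- stats::filter(t(m[idx, , drop = FALSE]), hc, sides = 2)
    f0[idx, ] <- t(fi)
  }
  # clipped windows at the edges: exact polynomial fit on the available part
  for (t in seq_len(half)) {
    win <- 1:(t + half)
    Xw <- outer(win - t, 0:degree, "^")
    h <- as.numeric(Xw[t, , drop = FALSE] %*% solve(crossprod(Xw), t(Xw)))
    f0[, t] <- m[, win, drop = FALSE] %*% h
    win2 <- (n_t - t - half + 1):n_t
    Xw2 <- outer(win2 - (n_t - t + 1), 0:degree, "^")
    h2 <- as.numeric(Xw2[length(win2) - t + 1, , drop = FALSE] %*%
                       solve(crossprod(Xw2), t(Xw2)))
    f0[, n_t - t + 1] <- m[, win2, drop = FALSE] %*% h2
  }
  f0
}

#' Pixelwise dF/F of a widefield movie
#'
#' The temporal baseline F0 of each pixel is a degree-3 polynomial fit
#' within a centered 15 s sliding window (clipped at the movie edges); the
#' output is the percent change (F - F0) / F0 * 100. Pixels where F0 drops
#' to zero or below at any frame are flagged invalid.
#'
#' @param movie a `widefield_movie`
#' @param window_s sliding window length in seconds (default 15)
#' @param degree polynomial degree (default 3)
#' @return object of class `dff_movie`: list with `dff` (pixels x frames,
#'   percent), `valid` (logical per pixel), plus geometry/schedule carried
#'   over
#' @export
preprocess_movie <- function(movie, window_s = 15, degree = 3) {
  fr <- movie$frame_rate
  half <- floor(window_s * fr / 2)
  f0 <- sliding_poly_baseline(movie$frames, half, degree)
  valid <- !apply(f0 <= 0, 1, any)
  dff <- (movie$frames - f0) / f0 * 100
  dff[!valid, ] <- NA_real_
  structure(list(dff = dff, valid = valid, height = movie$height,
                 width = movie$width, frame_rate = fr,
                 schedule = movie$schedule, truth = movie$truth),
            class = "dff_movie")
}

#' Tone-evoked response amplitude of one pixel trace
#'
#' Baseline mean and sd come from the 2 s prestimulus frames of each event;
#' the response is the maximum over the 750 ms post-onset window of the
#' frame value averaged with its preceding and following frames; the
#' repetition is evoked iff its z-score exceeds 2 (strictly). Repetitions
#' with zero prestimulus sd are skipped with a warning.
#'
#' @param trace dF/F trace of one pixel
#' @param onsets event onset frames
#' @param frame_rate Hz
#' @param pre_s prestimulus baseline window (default 2)
#' @param post_s response search window (default 0.75)
#' @param z_threshold evoked threshold (default 2, strict)
#' @return data.frame: onset, amplitude (baseline-subtracted), z, evoked
#' @export
evoked_amplitude <- function(trace, onsets, frame_rate, pre_s = 2,
                             post_s = 0.75, z_threshold = 2) {
  ev <- evoked_table(matrix(trace, nrow = 1), onsets, frame_rate, pre_s,
                     post_s, z_threshold)
  data.frame(onset = onsets, amplitude = ev$amp[1, ], z = ev$z[1, ],
             evoked = ev$evoked[1, ])
}

# vectorized evoked detection over all pixels (rows of dff)
evoked_table <- function(dff, onsets, frame_rate, pre_s = 2, post_s = 0.75,
                         z_threshold = 2) {
  npre <- floor(pre_s * frame_rate)
  npost <- floor(post_s * frame_rate)
  n_ev <- length(onsets)
  npx <- nrow(dff)
  amp <- z <- matrix(NA_real_, npx, n_ev)
  evoked <- matrix(NA, npx, n_ev)
  degenerate <- 0L
  for (e in seq_len(n_ev)) {
    o <- onsets[e]
    if (o - npre < 1) stop("insufficient prestimulus frames before onset ", o)
    pre <- dff[, (o - npre):(o - 1), drop = FALSE]
    mu <- rowMeans(pre)
    sdv <- sqrt(pmax(rowSums((pre - mu)^2) / (npre - 1), 0))
    best <- rep(-Inf, npx)
    for (j in o:(o + npost - 1)) {
      a3 <- (dff[, j - 1] + dff[, j] + dff[, j + 1]) / 3
      best <- pmax(best, a3)
    }
    a <- best - mu
    amp[, e] <- a
    ok <- sdv > 0
    z[ok, e] <- a[ok] / sdv[ok]
    evoked[ok, e] <- z[ok, e] > z_threshold
    evoked[!ok, e] <- NA
    degenerate <- degenerate + sum(!ok & !is.na(sdv))
  }
  if (degenerate > 0)
    warning(degenerate, " pixel-repetition(s) skipped (zero prestimulus sd)")
  list(amp = amp, z = z, evoked = evoked)
}

#' Per-pixel best-frequency map from evoked-response tables
#'
#' For each tone, a frequency-specific response amplitude is defined only
#' when at least `min_evoked` of the repetitions were tone-evoked, as the
#' mean of the evoked amplitudes. The best frequency of a pixel is the tone
#' with the highest mean amplitude (ties toward the lower frequency); pixels
#' with no qualifying tone are non-responsive.
#'
#' @param dffm a `dff_movie` (from [preprocess_movie()])
#' @param min_evoked minimum evoked repetitions per tone (default 4)
#' @param z_threshold evoked z threshold (default 2)
#' @param fov_id label carried into the map
#' @return object of class `pixel_bf_map`: list with matrices `bf_khz`,
#'   `amplitude`, `norm_amp` (in [0, 1]), `responsive`, plus geometry
#' @export
pixel_bf <- function(dffm, min_evoked = 4, z_threshold = 2, fov_id = "WF1") {
  sched <- dffm$schedule
  ev <- evoked_table(dffm$dff, sched$onset_frame, dffm$frame_rate,
                     z_threshold = z_threshold)
  tones <- sort(unique(sched$tone_khz))
  npx <- nrow(dffm$dff)
  mean_amp <- matrix(NA_real_, npx, length(tones))
  qualified <- matrix(FALSE, npx, length(tones))
  for (k in seq_along(tones)) {
    cols <- which(sched$tone_khz == tones[k])
    evk <- ev$evoked[, cols, drop = FALSE]
    evk[is.na(evk)] <- FALSE
    n_ev <- rowSums(evk)
    s <- rowSums(ev$amp[, cols, drop = FALSE] * evk, na.rm = TRUE)
    mean_amp[, k] <- ifelse(n_ev > 0, s / n_ev, NA_real_)
    qualified[, k] <- n_ev >= min_evoked
  }
  bf <- rep(NA_real_, npx)
  best <- rep(-Inf, npx)
  for (k in seq_along(tones)) {   # increasing frequency; ties keep lower
    cand <- qualified[, k] & !is.na(mean_amp[, k]) & mean_amp[, k] > best
    bf[cand] <- tones[k]
    best[cand] <- mean_amp[cand, k]
  }
  responsive <- !is.na(bf)
  amplitude <- ifelse(responsive, best, NA_real_)
  mx <- suppressWarnings(max(amplitude, na.rm = TRUE))
  norm_amp <- if (is.finite(mx) && mx > 0) amplitude / mx else amplitude
  H <- dffm$height; W <- dffm$width
  structure(list(bf_khz = matrix(bf, H, W),
                 amplitude = matrix(amplitude, H, W),
                 norm_amp = matrix(norm_amp, H, W),
                 responsive = matrix(responsive, H, W),
                 height = H, width = W, fov_id = fov_id),
            class = "pixel_bf_map")
}

#' Merge overlapping per-FOV best-frequency maps
#'
#' All maps must live on the same (global) pixel grid. Amplitudes of each
#' FOV are normalized to that FOV's maximum; where maps overlap, the BF with
#' the higher normalized amplitude wins.
#'
#' @param maps list of `pixel_bf_map` objects on a shared grid
#' @return merged `pixel_bf_map`
#' @export
merge_fov_maps <- function(maps) {
  if (!length(maps)) stop("no maps supplied")
  dims <- vapply(maps, function(m) c(m$height, m$width), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps are not registered to a shared pixel grid")
  H <- maps[[1]]$height; W <- maps[[1]]$width
  bf <- matrix(NA_real_, H, W)
  amp <- matrix(NA_real_, H, W)
  norm <- matrix(-Inf, H, W)
  for (m in maps) {
    na <- m$norm_amp
    take <- !is.na(na) & (is.na(bf) | na > norm)
    bf[take] <- m$bf_khz[take]
    amp[take] <- m$amplitude[take]
    norm[take] <- na[take]
  }
  norm[!is.finite(norm)] <- NA_real_
  structure(list(bf_khz = bf, amplitude = amp, norm_amp = norm,
                 responsive = !is.na(bf), height = H, width = W,
                 fov_id = "merged"),
            class = "pixel_bf_map")
}
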