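# Frequency tuning: responsiveness test, frequency response areas,
# Gaussian-fit classification, best frequency, bandwidth.

#' Two-group one-way ANOVA on pre- vs post-stimulus means
#'
#' With two groups the one-way ANOVA F statistic equals the squared pooled
#' t statistic; p from F(1, n_pre + n_post - 2).
#'
#' @param pre,post numeric vectors of per-repetition window means
#' @return p-value, or `NA` when both groups have zero variance
#' @keywords internal
anova2_p <- function(pre, post) {
  n1 <- length(pre); n2 <- length(post)
  v1 <- stats::var(pre); v2 <- stats::var(post)
  if (v1 == 0 && v2 == 0) return(NA_real_)
  gm <- mean(c(pre, post))
  ssb <- n1 * (mean(pre) - gm)^2 + n2 * (mean(post) - gm)^2
  ssw <- (n1 - 1) * v1 + (n2 - 1) * v2
  f <- ssb / (ssw / (n1 + n2 - 2))
  stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE)
}

# vectorized pre/post ANOVA over the columns of two rep x combo matrices
anova2_p_matrix <- function(pre, post) {
  n1 <- nrow(pre); n2 <- nrow(post)
  m1 <- colMeans(pre); m2 <- colMeans(post)
  v1 <- (colSums(pre^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(post^2) - n2 * m2^2) / (n2 - 1)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- (n1 - 1) * v1 + (n2 - 1) * v2
  p <- stats::pf(ssb / (ssw / (n1 + n2 - 2)), 1, n1 + n2 - 2,
                 lower.tail = FALSE)
  p[v1 == 0 & v2 == 0] <- NA_real_
  p
}

#' Extract pre-/post-stimulus window means from a spike-probability trace
#'
#' @param spikes spike-probability trace
#' @param protocol a `stimulus_protocol`
#' @param window_s window length in seconds (default 0.4); the window spans
#'   `floor(window_s * frame_rate)` frames from (and including) the onset
#'   frame, and symmetrically before it
#' @return data.frame: sound_id, freq_khz, spl_db, rep, pre, post
#' @export
trial_windows <- function(spikes, protocol, window_s = 0.4) {
  ev <- protocol$events
  w <- floor(window_s * protocol$frame_rate)
  pre <- vapply(ev$onset_frame, function(o)
    mean(spikes[max(o - w, 1):(o - 1)]), numeric(1))
  post <- vapply(ev$onset_frame, function(o)
    mean(spikes[o:min(o + w - 1, length(spikes))]), numeric(1))
  data.frame(sound_id = ev$sound_id, freq_khz = ev$freq_khz,
             spl_db = ev$spl_db, rep = ev$rep, pre = pre, post = post,
             stringsAsFactors = FALSE)
}

#' Test whether a neuron is pure-tone responsive
#'
#' For each of the frequency x SPL combinations, the per-repetition
#' pre-window means are compared with the post-window means by a one-way
#' ANOVA (two groups). The neuron is responsive if any combination reaches
#' p < alpha. No multiple-comparison correction is applied (by design).
#' Combinations with zero variance in both groups are skipped with a
#' warning.
#'
#' @param trials data.frame as returned by [trial_windows()] (columns
#'   freq_khz, spl_db, rep, pre, post), clean repetitions only
#' @param alpha significance level (default 0.01)
#' @return logical; attribute `p_values` holds the per-combination p-values
#' @export
test_pt_responsive <- function(trials, alpha = 0.01) {
  combo <- interaction(trials$freq_khz, trials$spl_db, drop = TRUE)
  p <- vapply(split(trials, combo), function(d) anova2_p(d$pre, d$post),
              numeric(1))
  if (anyNA(p))
    warning(sum(is.na(p)), " combination(s) skipped (zero variance)")
  structure(any(p < alpha, na.rm = TRUE), p_values = p)
}

#' Build a frequency response area
#'
#' Trial responses are averaged into the 17 x 5 frequency/SPL grid; mean
#' post-stimulus responses of each frequency are then averaged across SPLs,
#' giving a single mean value per frequency. Contaminated repetitions are
#' excluded first.
#'
#' @param trials data.frame: freq_khz, spl_db, rep, response (one neuron)
#' @param mask optional [exclude_running()] result or data.frame with
#'   `sound_id`/`freq_khz`+`spl_db`, `rep`, `clean`
#' @return object of class `fra`: list with `grid_means` (freq x SPL),
#'   `freq_means` (per frequency, averaged across SPLs), `freqs`, `spls`,
#'   `trials`
#' @export
build_fra <- function(trials, mask = NULL) {
  if (!is.null(mask)) {
    m <- if (inherits(mask, "repetition_mask")) mask$mask else mask
    if (!is.null(m$freq_khz)) {
      key <- paste(trials$freq_khz, trials$spl_db, trials$rep)
      mkey <- paste(m$freq_khz, m$spl_db, m$rep)
    } else {
      key <- paste(trials$sound_id, trials$rep)
      mkey <- paste(m$sound_id, m$rep)
    }
    clean <- m$clean[match(key, mkey)]
    # rows absent from the mask are assumed clean
    trials <- trials[is.na(clean) | clean, , drop = FALSE]
  }
  build_fra_core(trials)
}

build_fra_core <- function(trials) {
  freqs <- sort(unique(trials$freq_khz))
  spls <- sort(unique(trials$spl_db))
  counts <- table(factor(trials$freq_khz, levels = freqs),
                  factor(trials$spl_db, levels = spls))
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)
    stop("no clean repetitions for combination(s): ",
         paste(sprintf("%.2f kHz/%d dB", freqs[bad[, 1]],
                       spls[bad[, 2]]), collapse = ", "))
  }
  grid <- tapply(trials$response,
                 list(factor(trials$freq_khz, levels = freqs),
                      factor(trials$spl_db, levels = spls)), mean)
  structure(list(grid_means = grid, freq_means = rowMeans(grid),
                 freqs = freqs, spls = spls, trials = trials),
            class = "fra")
}
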