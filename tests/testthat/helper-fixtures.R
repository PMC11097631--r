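# Shared fixtures, built in code at test time.

oct_grid <- function() khz_to_oct(pt_frequencies())

# frequency vector of a planted unimodal Gaussian on the 17-tone grid
uni_vec <- function(A = 1, B = 2, C = 0.5, D = 0.05, noise_sd = 0,
                    rectify = TRUE) {
  x <- oct_grid()
  y <- A * exp(-((x - B) / C)^2) + D
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  if (rectify) y <- pmax(y, 0)
  y
}

bi_vec <- function(A1 = 1, B1 = 1, C1 = 0.5, A2 = 0.7, B2 = 3, C2 = 0.5,
                   D = 0.05, noise_sd = 0) {
  x <- oct_grid()
  y <- A1 * exp(-((x - B1) / C1)^2) + A2 * exp(-((x - B2) / C2)^2) + D
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  pmax(y, 0)
}

# tiny trial table covering the full 17 x 5 grid
trial_table <- function(fun = function(f, s, r) 1, n_rep = 5) {
  g <- expand.grid(freq_khz = pt_frequencies(), spl_db = pt_spls(),
                   rep = seq_len(n_rep), KEEP.OUT.ATTRS = FALSE)
  g$response <- mapply(fun, g$freq_khz, g$spl_db, g$rep)
  g
}

# block-structured sound correlation matrix with explicit reliability
block_corr <- function(sizes, within = 0.9, between = 0, reliability = 0.95,
                       n_extra = 0, extra_r = 0) {
  S <- sum(sizes) + n_extra
  lab <- c(rep(seq_along(sizes), sizes), rep(0L, n_extra))
  m <- matrix(between, S, S)
  for (k in seq_along(sizes)) {
    idx <- which(lab == k)
    m[idx, idx] <- within
  }
  if (n_extra > 0) {
    idx <- which(lab == 0L)
    m[idx, ] <- extra_r; m[, idx] <- extra_r
    m[idx, idx] <- extra_r
  }
  diag(m) <- reliability
  diag(m)[lab == 0L] <- extra_r
  rownames(m) <- colnames(m) <- sprintf("s%02d", seq_len(S))
  attr(m, "labels") <- lab
  m
}

# small pixel_bf_map built directly (no movie) with a radial planted crest
toy_bf_map <- function(H = 64, W = 64, hub = c(30, 32), crest = 18,
                       margin = 8) {
  px_x <- rep(seq_len(W), each = H)
  px_y <- rep(seq_len(H), times = W)
  d <- sqrt((px_x - hub[1])^2 + (px_y - hub[2])^2)
  bf_oct <- pmin(pmax(ifelse(d <= crest, 4 * d / crest,
                             4 - 3 * (d - crest) / crest), 0), 4)
  bf_oct <- round(bf_oct)   # snap to the 5-tone octave set
  responsive <- px_x > margin & px_x <= W - margin &
    px_y > margin & px_y <= H - margin
  bf <- ifelse(responsive, oct_to_khz(bf_oct), NA_real_)
  structure(list(bf_khz = matrix(bf, H, W),
                 amplitude = matrix(ifelse(responsive, 1, NA_real_), H, W),
                 norm_amp = matrix(ifelse(responsive, 1, NA_real_), H, W),
                 responsive = matrix(responsive, H, W),
                 height = H, width = W, fov_id = "toy",
                 hub = hub, crest = crest, margin = margin),
            class = "pixel_bf_map")
}
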