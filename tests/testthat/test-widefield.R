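# dF/F baseline, evoked detection, pixel BF, FOV merging, reversal
# scanning and parcellation.

mini_movie <- function(frames_mat, H, W, fr = 10, sched = NULL) {
  structure(list(frames = frames_mat, height = H, width = W,
                 frame_rate = fr, schedule = sched, truth = NULL),
            class = "widefield_movie")
}

test_that("preprocess_movie removes slow structure, keeps fast events", {
  fr <- 10; T <- 400
  tt <- seq_len(T)
  # constant movie -> dF/F identically 0
  cm <- mini_movie(matrix(100, 4, T), 2, 2)
  expect_true(all(abs(preprocess_movie(cm)$dff) < 1e-9))

  # slow cubic drift is absorbed exactly by the degree-3 fit
  drift <- 100 + 0.01 * tt + 1e-4 * tt^2 - 1e-7 * tt^3
  dm <- mini_movie(matrix(rep(drift, each = 4), 4, T), 2, 2)
  expect_true(all(abs(preprocess_movie(dm)$dff) < 0.5))

  # a 1 s step of +10% rides on top of the fitted baseline
  f <- rep(100, T); f[200:209] <- 110
  sm <- mini_movie(matrix(rep(f, each = 1), 1, T), 1, 1)
  dff <- preprocess_movie(sm)$dff
  expect_gt(max(dff[1, 195:215]), 8)
  expect_lt(max(dff[1, 195:215]), 12)

  # scale invariance
  m1 <- matrix(rep(drift, each = 4), 4, T) + rnorm(4 * T)
  d1 <- preprocess_movie(mini_movie(m1, 2, 2))$dff
  d2 <- preprocess_movie(mini_movie(3.3 * m1, 2, 2))$dff
  expect_equal(d1, d2, tolerance = 1e-9)

  expect_error(preprocess_movie(mini_movie(matrix(1, 1, 50), 1, 1)),
               "shorter")
})

test_that("evoked_amplitude implements the 3-frame z rule", {
  fr <- 10
  trace <- rep(0, 100)
  set.seed(1)
  base_noise <- rnorm(100, 0, 1)
  trace <- base_noise
  onset <- 41

  # post window equal to baseline -> not evoked
  ev0 <- evoked_amplitude(trace, onset, fr)
  expect_false(ev0$evoked[1])

  # spike of baseline + 10 sd flanked by baseline-level frames
  tr2 <- rep(0, 100); tr2[1:40] <- rnorm(40, 0, 1)
  sd_b <- sd(tr2[21:40]); mu_b <- mean(tr2[21:40])
  tr2[43] <- mu_b + 10 * sd_b
  ev2 <- evoked_amplitude(tr2, onset, fr)
  # amplitude ~ (10 sd + 0 + 0)/3 relative to baseline
  expect_equal(ev2$amplitude[1],
               mean(c(tr2[42], tr2[43], tr2[44])) - mu_b, tolerance = 1e-12)
  expect_true(ev2$evoked[1])

  # z exactly 2 is NOT evoked (strict >)
  tr3 <- rep(c(-1, 1), 50)   # baseline sd known
  mu3 <- mean(tr3[21:40]); sd3 <- sd(tr3[21:40])
  tr3[42:44] <- mu3 + 2 * sd3   # 3-frame average exactly 2 sd above
  ev3 <- evoked_amplitude(tr3, onset, fr)
  expect_equal(ev3$z[1], 2, tolerance = 1e-9)
  expect_false(ev3$evoked[1])

  # zero baseline sd -> skipped with warning
  tr4 <- rep(5, 100); tr4[45] <- 50
  expect_warning(ev4 <- evoked_amplitude(tr4, onset, fr), "zero prestimulus")
  expect_true(is.na(ev4$evoked[1]))
})

test_that("pixel_bf equals a brute-force reimplementation", {
  # random small stack: 16 pixels x 5 tones x 16 reps, direct dff input
  set.seed(9)
  fr <- 10
  tones <- c(4, 8, 16, 32, 64)
  sched <- data.frame(tone_khz = rep(tones, 16),
                      rep = rep(1:16, each = 5))
  n_ev <- nrow(sched)
  sched$onset_frame <- 25 + (seq_len(n_ev) - 1) * 40
  T <- max(sched$onset_frame) + 30
  npx <- 16
  dff <- matrix(rnorm(npx * T, 0, 1), npx, T)
  # plant strong responses: pixel i prefers tone (i %% 5) + 1
  pref <- (seq_len(npx) - 1) %% 5 + 1
  for (e in seq_len(n_ev)) {
    k <- match(sched$tone_khz[e], tones)
    hit <- which(pref == k)
    dff[hit, sched$onset_frame[e] + 2] <-
      dff[hit, sched$onset_frame[e] + 2] + 25
  }
  dffm <- structure(list(dff = dff, valid = rep(TRUE, npx), height = 4,
                         width = 4, frame_rate = fr, schedule = sched),
                    class = "dff_movie")
  map <- pixel_bf(dffm)

  # brute force: naive loops over pixels/tones/reps
  brute_bf <- rep(NA_real_, npx)
  for (p in seq_len(npx)) {
    best_amp <- -Inf; best_tone <- NA
    for (k in seq_along(tones)) {
      amps <- c(); n_ev_k <- 0
      for (e in which(sched$tone_khz == tones[k])) {
        o <- sched$onset_frame[e]
        mu <- mean(dff[p, (o - 20):(o - 1)])
        sdv <- sd(dff[p, (o - 20):(o - 1)])
        cand <- sapply(o:(o + 6), function(j) mean(dff[p, (j - 1):(j + 1)]))
        a <- max(cand) - mu
        if (a / sdv > 2) { amps <- c(amps, a); n_ev_k <- n_ev_k + 1 }
      }
      if (n_ev_k >= 4 && mean(amps) > best_amp) {
        best_amp <- mean(amps); best_tone <- tones[k]
      }
    }
    brute_bf[p] <- best_tone
  }
  expect_equal(as.vector(map$bf_khz), brute_bf)
  expect_true(all(map$norm_amp[map$responsive] <= 1))
})

test_that("pixel_bf requires at least 4 evoked repetitions", {
  fr <- 10
  tones <- c(4, 8)
  sched <- data.frame(tone_khz = rep(tones, 16), rep = rep(1:16, each = 2))
  sched$onset_frame <- 25 + (seq_len(nrow(sched)) - 1) * 40
  T <- max(sched$onset_frame) + 30
  dff <- matrix(rnorm(2 * T, 0, 1), 2, T)
  # pixel 1: only 3 strong responses to 4 kHz; pixel 2: 8 strong responses
  ev4 <- which(sched$tone_khz == 4)
  for (e in ev4[1:3]) dff[1, sched$onset_frame[e] + 2] <- 30
  for (e in ev4[1:8]) dff[2, sched$onset_frame[e] + 2] <- 30
  dffm <- structure(list(dff = dff, valid = c(TRUE, TRUE), height = 1,
                         width = 2, frame_rate = fr, schedule = sched),
                    class = "dff_movie")
  map <- pixel_bf(dffm)
  expect_true(is.na(map$bf_khz[1, 1]))
  expect_equal(map$bf_khz[1, 2], 4)
})

test_that("merge_fov_maps normalizes and resolves overlaps", {
  mk <- function(bf, amp) {
    structure(list(bf_khz = bf, amplitude = amp,
                   norm_amp = amp / max(amp, na.rm = TRUE),
                   responsive = !is.na(bf), height = nrow(bf),
                   width = ncol(bf), fov_id = "m"),
              class = "pixel_bf_map")
  }
  bf1 <- matrix(NA_real_, 4, 4); amp1 <- matrix(NA_real_, 4, 4)
  bf1[1:3, 1:3] <- 8;  amp1[1:3, 1:3] <- 10
  bf2 <- matrix(NA_real_, 4, 4); amp2 <- matrix(NA_real_, 4, 4)
  bf2[3:4, 3:4] <- 32; amp2[3:4, 3:4] <- 2
  m1 <- mk(bf1, amp1); m2 <- mk(bf2, amp2)

  # single map: amplitudes rescaled to max 1, BFs unchanged
  s <- merge_fov_maps(list(m1))
  expect_equal(max(s$norm_amp, na.rm = TRUE), 1)
  expect_equal(s$bf_khz, bf1)

  # overlap at (3,3): FOV-A normalized 1.0 beats FOV-B 1.0? make B weaker
  m2$norm_amp[3, 3] <- 0.4
  mg <- merge_fov_maps(list(m1, m2))
  expect_equal(mg$bf_khz[3, 3], 8)
  expect_equal(mg$bf_khz[4, 4], 32)

  # disjoint FOVs: plain union
  bf3 <- matrix(NA_real_, 4, 4); bf3[1, 4] <- 64
  amp3 <- matrix(NA_real_, 4, 4); amp3[1, 4] <- 5
  mu <- merge_fov_maps(list(m1, mk(bf3, amp3)))
  expect_equal(mu$bf_khz[1, 4], 64)
  expect_equal(mu$bf_khz[2, 2], 8)
  expect_equal(sum(mu$responsive), sum(m1$responsive) + 1)

  expect_error(merge_fov_maps(list(m1, mk(matrix(8, 3, 3),
                                          matrix(1, 3, 3)))),
               "registered")
})

test_that("radial scanning finds the planted crest and the AC end", {
  map <- toy_bf_map(H = 72, W = 72, hub = c(33, 36), crest = 18, margin = 11)
  pr <- find_reversals_and_boundary(map, hubs = list(c(33, 36)),
                                    n_dir = 180)
  expect_gt(nrow(pr$reversals), 0.8 * 180)
  expect_gte(mean(abs(pr$reversals$radius - 18) <= 5), 0.9)
  # boundary points fall inside the planted silent margin
  bx <- round(pr$boundary$x); by <- round(pr$boundary$y)
  expect_true(all(bx <= 11 | bx > 72 - 11 | by <= 11 | by > 72 - 11))

  # monotone profile (no interior max): no reversal reported
  mono <- toy_bf_map(H = 64, W = 64, hub = c(32, 32), crest = 60, margin = 8)
  pm <- find_reversals_and_boundary(mono, hubs = list(c(32, 32)),
                                    n_dir = 60, fit = "smooth")
  # crest beyond the responsive region -> profiles rise monotonically
  expect_lt(nrow(pm$reversals), 10)

  # hub detection lands near the planted hub
  hubs <- find_hubs(map)
  expect_lt(sqrt(sum((hubs[[1]] - c(33, 36))^2)), 6)
})

test_that("parcellate assigns labels in import and auto modes", {
  map <- toy_bf_map(H = 48, W = 48, hub = c(22, 24), crest = 12, margin = 6)

  # import: rectangles partition their interiors exactly
  r1 <- data.frame(x = c(10, 24, 24, 10, 10), y = c(10, 10, 38, 38, 10))
  r2 <- data.frame(x = c(24, 40, 40, 24, 24), y = c(10, 10, 38, 38, 10))
  pc <- parcellate(map, mode = "import", borders = list(A1 = r1, AAF = r2))
  expect_equal(pc$labels[20, 15], "A1")   # (row y=20, col x=15)
  expect_equal(pc$labels[20, 30], "AAF")
  expect_equal(pc$labels[5, 5], "none")
  open_b <- r1[1:4, ]
  expect_error(parcellate(map, mode = "import", borders = list(A1 = open_b)),
               "not closed")

  # auto: border tracks the planted crest ring
  pr <- find_reversals_and_boundary(map, hubs = list(c(22, 24)), n_dir = 120)
  pa <- parcellate(map, pr, mode = "auto")
  b <- pa$border
  d_hub <- sqrt((b[, 1] - 22)^2 + (b[, 2] - 24)^2)
  expect_gte(mean(abs(d_hub - 12) <= 5), 0.8)
  expect_setequal(intersect(unique(as.vector(pa$labels)),
                            c("A1", "AAF", "A2")),
                  c("A1", "AAF", "A2"))

  # no reversals: responsive region labelled unassigned
  empty <- pr; empty$reversals <- pr$reversals[0, ]
  pu <- parcellate(map, empty, mode = "auto")
  expect_true(all(pu$labels[map$responsive] == "unassigned"))
})
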