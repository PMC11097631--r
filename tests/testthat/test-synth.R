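# Synthetic generators: planted-truth consistency, determinism, stated
# degenerate cases.

test_that("generate_population plants a monotone gradient and classes", {
  cfg <- synth_config(n_neurons = 500, scatter_sd = 0, rng_seed = 8)
  pop <- generate_population(cfg)
  tr <- pop$truth
  expect_equal(nrow(tr), 500)
  expect_true(all(tr$bf_khz >= 4 - 1e-9 & tr$bf_khz <= 64 + 1e-9))
  # zero scatter, gradient along x: BF monotone in x (up to axis clipping)
  interior <- tr$bf_oct > 0 & tr$bf_oct < 4
  expect_true(all(diff(tr$bf_oct[interior][order(tr$x[interior])]) >= 0))
  # iso-BF bands have zero IQR
  band <- tr[tr$x > 300 & tr$x < 320 & interior, ]
  expect_lt(diff(range(band$bf_oct)), 0.1)

  # determinism: same seed twice -> bit-identical
  expect_identical(generate_population(cfg), pop)

  # degenerate mixture
  cfg1 <- synth_config(n_neurons = 1000,
                       class_fractions = c(single = 1, double = 0,
                                           irregular = 0), rng_seed = 1)
  expect_true(all(generate_population(cfg1)$truth$class == "single"))

  bad <- cfg; bad$scatter_sd <- NaN
  expect_error(generate_population(bad), "non-finite")
})

test_that("generate_trial_responses realizes the planted tuning", {
  cfg <- synth_config(n_neurons = 12, trial_noise_sd = 0, rng_seed = 4)
  pop <- generate_population(cfg)
  prot <- pt_protocol(n_rep = 3, seed = 2)
  tr <- generate_trial_responses(pop, prot)

  # noiseless single-peak: response at the grid tone nearest the planted BF
  # is the grid maximum for every SPL
  for (id in pop$truth$neuron_id[pop$truth$class == "single"][1:3]) {
    truth <- pop$truth[pop$truth$neuron_id == id, ]
    d <- tr[tr$neuron_id == id, ]
    for (s in pt_spls()) {
      ds <- d[d$spl_db == s, ]
      best <- ds$freq_khz[which.max(ds$response)]
      expect_equal(khz_to_oct(best),
                   khz_to_oct(pt_frequencies())[
                     which.min(abs(khz_to_oct(pt_frequencies()) - truth$B1))])
    }
  }
  # irregular (flat) neurons: all responses equal D
  irr <- pop$truth$neuron_id[pop$truth$class == "irregular"][1]
  expect_true(all(abs(tr$response[tr$neuron_id == irr] -
                        pop$truth$D[1]) < 1e-12))

  # noise > 0: per-cell sample means concentrate as 4 sd / sqrt(n_rep)
  cfgn <- synth_config(n_neurons = 120, trial_noise_sd = 0.3, rng_seed = 6,
                       class_fractions = c(single = 1, double = 0,
                                           irregular = 0))
  popn <- generate_population(cfgn)
  protn <- pt_protocol(n_rep = 10, spls = 70, seed = 3)
  trn <- generate_trial_responses(popn, protn)
  # compare the observed mean at each neuron's first tone with the planted
  # mean (rectified-normal oracle: bias is negligible when mu >> sd)
  tol <- 4 * 0.3 / sqrt(10)
  ok <- vapply(seq_len(120), function(i) {
    truth <- popn$truth[i, ]
    tone <- pt_frequencies()[which.min(abs(khz_to_oct(pt_frequencies()) -
                                             truth$B1))]
    d <- trn[trn$neuron_id == truth$neuron_id & trn$freq_khz == tone, ]
    mu <- truth$A1 * exp(-((khz_to_oct(tone) - truth$B1) / truth$C1)^2) *
      tonotopr:::spl_gain(70) + truth$D
    abs(mean(d$response) - mu) < tol
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  badp <- prot; badp$events$freq_khz[1] <- 120
  expect_error(generate_trial_responses(pop, badp), "outside")
})

test_that("generate_traces satisfies the PSNR and speed contracts", {
  # closed-form PSNR check: flat neuropil baseline of known noise sd
  cfg <- synth_config(n_neurons = 5, neuropil_baseline = 0,
                      neuropil_drift_amp = 0, neuropil_noise_sd = 2,
                      trace_noise_sd = 0.01, transient_amp = 500,
                      trial_noise_sd = 0, rng_seed = 12)
  pop <- generate_population(cfg)
  # long pauses so transients decay fully before the next event
  prot <- pt_protocol(n_rep = 3, spls = 70, pause_s = 3, seed = 5)
  tt <- generate_traces(pop, prot)
  for (rec in tt$recordings[1:3]) {
    expect_lt(abs(compute_psnr(rec) - 20 * log10(500 / 2)), 0.5)
  }

  # run probability 0 -> speed identically zero, nothing excluded
  expect_true(all(tt$speed == 0))
  expect_true(exclude_running(prot, tt$speed, min_clean = 3)$fov_valid)

  # determinism
  tt2 <- generate_traces(pop, prot)
  expect_identical(tt2$recordings[[1]]$raw, tt$recordings[[1]]$raw)

  # run probability > 0 produces bouts above threshold
  cfgr <- synth_config(n_neurons = 2, run_prob = 0.3, rng_seed = 3)
  popr <- generate_population(cfgr)
  ttr <- generate_traces(popr, prot)
  expect_gt(mean(ttr$speed > 1), 0.05)
})

test_that("generate_two_sessions plants ensembles and drift", {
  cfg <- ensemble_config(n_sounds = 12, n_ensembles = 3, n_neurons = 25,
                         drift_fraction = 0.4, rng_seed = 9)
  tw <- generate_two_sessions(cfg)
  expect_equal(dim(tw$session1), c(12, 10, 25))
  expect_equal(length(tw$truth$ens_of_sound), 12)
  expect_equal(length(tw$truth$drifted), 10)
  # undrifted neurons keep their loadings
  keep <- setdiff(1:25, tw$truth$drifted)
  expect_identical(tw$truth$loadings1[keep, ], tw$truth$loadings2[keep, ])
  expect_false(isTRUE(all.equal(tw$truth$loadings1[tw$truth$drifted, ],
                                tw$truth$loadings2[tw$truth$drifted, ])))

  expect_error(ensemble_config(n_sounds = 3, n_ensembles = 5), "more ensembles")

  # drift 0 / noise 0: sessions identical
  tw0 <- generate_two_sessions(ensemble_config(noise_sd = 0, rng_seed = 2))
  expect_identical(tw0$session1, tw0$session2)
})

test_that("reliability decreases along a trial-noise ladder", {
  rel <- vapply(c(0.02, 0.2, 0.6), function(ns) {
    mean(vapply(1:3, function(seed) {
      tw <- generate_two_sessions(
        ensemble_config(noise_sd = ns, rng_seed = 30 + seed))
      mean(diag(sound_correlation(tw$session1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("widefield generator plants a reversal and a silent margin", {
  cfg <- widefield_config(width = 64, height = 64, margin = 6,
                          pause_s = 2.5, lead_in_s = 3, noise_sd = 0,
                          drift_amp = 0, rng_seed = 1)
  mv <- generate_widefield_movie(cfg)
  tr <- mv$truth
  expect_equal(dim(mv$frames), c(64 * 64, ncol(mv$frames)))
  expect_true(all(!tr$responsive[1:6, ]))
  expect_equal(sort(unique(as.vector(tr$bf_khz[tr$responsive]))),
               c(4, 8, 16, 32, 64))
  # noiseless, driftless: per-pixel argmax of planted amplitude = truth BF
  best_tone <- cfg$tone_khz[apply(tr$amp, 1, which.max)]
  resp <- as.vector(tr$responsive)
  expect_true(all(best_tone[resp] == as.vector(tr$bf_khz)[resp]))
  # determinism
  expect_identical(generate_widefield_movie(cfg)$frames[1:50, 1:5],
                   mv$frames[1:50, 1:5])
  expect_error(widefield_config(width = 64, height = 64, hub = c(99, 2)),
               "hub")
  expect_error(widefield_config(width = 16, height = 16), "64")
})
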