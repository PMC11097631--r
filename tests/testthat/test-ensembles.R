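# Cell vectors, sound correlation, clustering, cross-week stability.

test_that("build_cell_vectors averages the stated window", {
  prot <- sound_protocol(paste0("s", 1:4), n_rep = 3, frame_rate = 29.76,
                         seed = 2)
  n_neur <- 5
  spikes <- matrix(0.7, n_neur, prot$n_frames)

  # constant trace c -> every entry c
  cv <- build_cell_vectors(spikes, prot)
  expect_true(all(cv == 0.7))
  expect_equal(dim(cv), c(4, 3, 5))

  # 0.4 s at 29.76 Hz -> 11 frames averaged from the onset inclusive
  sp2 <- matrix(0, 2, prot$n_frames)
  o <- prot$events$onset_frame[1]
  sp2[1, o + 0:10] <- 1      # exactly the 11-frame window
  sp2[1, o + 11] <- 99       # one frame past the window: ignored
  cv2 <- build_cell_vectors(sp2, prot)
  s1 <- prot$events$sound_id[1]; r1 <- prot$events$rep[1]
  expect_equal(unname(cv2[s1, r1, 1]), 1)

  # contaminated repetition dropped
  mask <- data.frame(sound_id = prot$events$sound_id,
                     rep = prot$events$rep, clean = TRUE)
  mask$clean[mask$sound_id == "s2" & mask$rep == 2] <- FALSE
  cv3 <- build_cell_vectors(spikes, prot, mask = mask)
  expect_true(all(is.na(cv3["s2", 2, ])))
  expect_true(all(!is.na(cv3["s1", , ])))

  # invalid FOV refused
  bad <- structure(list(mask = mask, clean_counts = c(s1 = 2),
                        fov_valid = FALSE, min_clean = 5),
                   class = "repetition_mask")
  expect_error(build_cell_vectors(spikes, prot, mask = bad), "FOV invalid")
})

test_that("sound_correlation equals a naive double-loop computation", {
  set.seed(3)
  arr <- array(runif(5 * 3 * 10), dim = c(5, 3, 10),
               dimnames = list(paste0("s", 1:5), NULL, NULL))
  sc <- sound_correlation(arr)
  expect_true(isSymmetric(unclass(sc)))
  for (a in 1:5) for (b in 1:5) {
    vals <- c()
    for (i in 1:3) for (j in 1:3) {
      if (a == b && i >= j) next
      vals <- c(vals, cor(arr[a, i, ], arr[b, j, ]))
    }
    expect_equal(sc[a, b], mean(vals), tolerance = 1e-12)
  }

  # identical vectors for all sounds/reps -> all entries 1
  one <- array(rep(1:6, each = 15), dim = c(5, 3, 6))
  # make them vary across neurons but identical across sounds/reps
  for (s in 1:5) for (r in 1:3) one[s, r, ] <- 1:6
  expect_true(all(abs(sound_correlation(one) - 1) < 1e-12))

  # disjoint halves: off-diagonal equals direct Pearson of the patterns
  half <- array(0, dim = c(2, 2, 10))
  half[1, , 1:5] <- 1; half[2, , 6:10] <- 1
  sch <- sound_correlation(half)
  expect_equal(sch[1, 2], cor(c(rep(1, 5), rep(0, 5)),
                              c(rep(0, 5), rep(1, 5))))
  expect_equal(sch[1, 2], -1)   # complementary binary patterns, n/2 split

  # zero-variance vectors excluded pairwise
  zv <- array(runif(2 * 2 * 8), dim = c(2, 2, 8))
  zv[1, 1, ] <- 5
  expect_warning(szv <- sound_correlation(zv), "zero-variance")
  expect_true(is.finite(szv[1, 2]))
  expect_error(sound_correlation(array(1, dim = c(3, 2, 5))),
               "zero variance")
})

test_that("cluster_sounds recovers planted block structure", {
  m <- block_corr(c(5, 5, 5), within = 0.9, between = 0)
  cr <- cluster_sounds(m)
  expect_equal(cr$n_clusters, 3)
  expect_equal(adjusted_rand_index(cr$labels, attr(m, "labels")), 1)
  expect_equal(cr$fraction_clustered, 1)
  # metrics match direct computation from the planted matrix
  expect_equal(cr$within_cor, 0.9)
  expect_equal(cr$between_cor, 0)
  expect_equal(cr$within_reliability, 0.95)

  # 3 blocks + 2 near-zero singletons: 3 clusters, 2 unclustered
  m2 <- block_corr(c(5, 5, 3), within = 0.85, between = 0.05,
                   n_extra = 2, extra_r = 0.02)
  cr2 <- cluster_sounds(m2)
  expect_equal(cr2$n_clusters, 3)
  expect_equal(sum(cr2$labels == 0), 2)
  expect_equal(cr2$fraction_clustered, 13 / 15)
  expect_equal(adjusted_rand_index(cr2$labels, attr(m2, "labels")), 1)

  # all entries equal: 0 or 1 cluster, metrics well-defined, no crash
  m3 <- matrix(0.5, 6, 6)
  cr3 <- cluster_sounds(m3)
  expect_lte(cr3$n_clusters, 1)
  expect_true(is.numeric(cr3$fraction_clustered))

  expect_error(cluster_sounds(matrix(0.5, 2, 2)), "at least 3")
  asym <- m; asym[1, 2] <- 0.99
  expect_error(cluster_sounds(asym), "symmetric")
})

test_that("cutree_hybrid is deterministic and validates deep_split", {
  m <- block_corr(c(4, 4), within = 0.8, between = 0.1)
  d <- 1 - m; diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  l1 <- cutree_hybrid(hc, d)
  expect_identical(l1, cutree_hybrid(hc, d))
  expect_equal(sort(unique(l1)), c(1, 2))
  expect_error(cutree_hybrid(hc, d, deep_split = 5), "deep_split")
  # deeper split settings never yield fewer clusters on this fixture
  n0 <- length(unique(cutree_hybrid(hc, d, deep_split = 0)))
  n4 <- length(unique(cutree_hybrid(hc, d, deep_split = 4)))
  expect_lte(n0, n4)
})

test_that("cross_week_cluster_similarity follows the counterpart rule", {
  mk <- function(labels) {
    structure(list(labels = stats::setNames(labels,
                                            paste0("s", seq_along(labels)))),
              class = "cluster_result")
  }
  a <- mk(c(1, 1, 1, 2, 2, 2, 3, 3, 3))

  expect_equal(cross_week_cluster_similarity(a, a), 1)

  # week-1 cluster split into two equal week-2 halves contributes 0.5
  b <- mk(c(1, 1, 1, 2, 2, 2, 3, 3, 4))
  a2 <- mk(c(1, 1, 1, 1, 2, 2, 2, 2, 0))
  b2 <- mk(c(1, 1, 3, 3, 2, 2, 4, 4, 0))
  expect_equal(cross_week_cluster_similarity(a2, b2), 0.5)

  # no week-2 clusters -> 0 with warning
  none <- mk(rep(0, 9))
  expect_warning(s0 <- cross_week_cluster_similarity(a, none), "no clusters")
  expect_equal(s0, 0)

  # permuted labels: agreement with a Monte-Carlo permutation oracle
  set.seed(7)
  l1 <- c(rep(1, 5), rep(2, 5), rep(3, 5))
  sims <- replicate(400, {
    cross_week_cluster_similarity(mk(l1), mk(sample(l1)))
  })
  # oracle: expected max-overlap of random same-size subsets, estimated by
  # an independent permutation stream
  oracle <- replicate(2000, {
    p <- sample(l1)
    mean(vapply(1:3, function(k)
      max(vapply(1:3, function(m)
        sum(l1 == k & p == m) / 5, numeric(1))), numeric(1)))
  })
  expect_lt(abs(mean(sims) - mean(oracle)), 0.03)
})

test_that("cross_week_neuron_correlation uses matched same-rep pairs", {
  set.seed(5)
  v1 <- array(runif(6 * 4 * 12), dim = c(6, 4, 12))

  expect_equal(cross_week_neuron_correlation(v1, v1), 1)

  # affine transform leaves Pearson unchanged
  expect_equal(cross_week_neuron_correlation(v1, 2.5 * v1 + 3), 1)

  # permuted neuron identities: near zero across seeds
  rs <- replicate(60, {
    perm <- sample(12)
    cross_week_neuron_correlation(v1, v1[, , perm])
  })
  expect_lt(abs(mean(rs)), 0.1)

  # fewer than 3 matched neurons -> NA
  expect_true(is.na(cross_week_neuron_correlation(v1[, , 1:2, drop = FALSE],
                                                  v1[, , 1:2, drop = FALSE])))
})

test_that("correlation matrices are invariant to a global affine gain", {
  # note: Pearson correlation across the neuron dimension is NOT invariant
  # to per-neuron gains (each neuron's gain reweights its contribution); a
  # common gain/offset applied to every neuron leaves it unchanged
  set.seed(11)
  arr <- array(runif(4 * 3 * 9), dim = c(4, 3, 9))
  expect_equal(unclass(sound_correlation(arr)),
               unclass(sound_correlation(2.7 * arr + 1.3)),
               tolerance = 1e-10)
})
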