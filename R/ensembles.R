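# Sound-ensemble analysis: cell vectors, sound-correlation matrices with
# reliability diagonals, clustering, and derived metrics.

#' Build population cell vectors per sound and repetition
#'
#' For every (sound, repetition), the activity of each neuron is averaged
#' over a fixed window from sound onset (0.4 s; 0.55 s when only complex
#' sounds are analyzed) and the values combined into one population vector.
#' The window spans `floor(window_s * frame_rate)` frames from the onset
#' frame inclusive. Contaminated repetitions are dropped (set NA).
#'
#' @param spike_mat neurons x frames matrix of spike probabilities (or a
#'   list of [neuron_recording()]s, whose `spikes` traces are stacked)
#' @param protocol a `stimulus_protocol`
#' @param mask optional [exclude_running()] result; if the FOV is invalid
#'   (fewer than 5 clean repetitions for some sound) the function refuses
#' @param window_s response window in seconds (default 0.4)
#' @return object of class `cell_vector_set`: array sound x rep x neuron
#'   (NA = contaminated), with sound ids as dimnames
#' @export
build_cell_vectors <- function(spike_mat, protocol, mask = NULL,
                               window_s = 0.4) {
  if (is.list(spike_mat) && !is.matrix(spike_mat))
    spike_mat <- do.call(rbind, lapply(spike_mat, `[[`, "spikes"))
  if (!is.null(mask) && inherits(mask, "repetition_mask") && !mask$fov_valid)
    stop("FOV invalid: fewer than ", mask$min_clean,
         " clean repetitions for at least one sound")
  ev <- protocol$events
  w <- floor(window_s * protocol$frame_rate)
  sounds <- unique(ev$sound_id)
  reps <- sort(unique(ev$rep))
  n_neur <- nrow(spike_mat)
  arr <- array(NA_real_, dim = c(length(sounds), length(reps), n_neur),
               dimnames = list(sounds, NULL, rownames(spike_mat)))
  mk <- if (is.null(mask)) NULL else
    if (inherits(mask, "repetition_mask")) mask$mask else mask
  for (i in seq_len(nrow(ev))) {
    if (!is.null(mk)) {
      hit <- mk$clean[mk$sound_id == ev$sound_id[i] & mk$rep == ev$rep[i]]
      if (length(hit) && !hit[1]) next
    }
    fr <- ev$onset_frame[i]:min(ev$onset_frame[i] + w - 1, ncol(spike_mat))
    arr[ev$sound_id[i], match(ev$rep[i], reps), ] <-
      rowMeans(spike_mat[, fr, drop = FALSE])
  }
  structure(arr, class = c("cell_vector_set", "array"), window_s = window_s)
}

#' Sound-by-sound correlation matrix with reliability diagonal
#'
#' Off-diagonal (a, b): the Pearson correlation between the cell vectors of
#' sound a (repetition i) and sound b (repetition j), averaged over all
#' repetition pairs. Diagonal (a, a): the same average over distinct pairs
#' i < j of the same sound — the response reliability. Zero-variance
#' vectors are excluded pairwise with a warning.
#'
#' @param vectors a `cell_vector_set` (sound x rep x neuron), or any such
#'   array
#' @return symmetric matrix of class `sound_correlation`
#' @export
sound_correlation <- function(vectors) {
  dm <- dim(vectors)
  S <- dm[1]; R <- dm[2]; N <- dm[3]
  if (R < 2) stop("need at least 2 repetitions")
  if (N < 3) stop("need at least 3 neurons")
  flat <- matrix(aperm(vectors, c(3, 1, 2)), nrow = N)  # N x (S*R)
  present <- colSums(is.na(flat)) == 0
  sds <- apply(flat, 2, stats::sd)
  usable <- present & !is.na(sds) & sds > 0
  if (!any(usable)) stop("all cell vectors have zero variance")
  if (any(present & !usable))
    warning(sum(present & !usable), " zero-variance vector(s) excluded")
  cc <- suppressWarnings(stats::cor(flat))
  cc[!usable, ] <- NA; cc[, !usable] <- NA
  idx_sound <- rep(seq_len(S), times = R)
  idx_rep <- rep(seq_len(R), each = S)
  out <- matrix(NA_real_, S, S,
                dimnames = list(dimnames(vectors)[[1]],
                                dimnames(vectors)[[1]]))
  for (a in seq_len(S)) for (b in a:S) {
    ia <- which(idx_sound == a); ib <- which(idx_sound == b)
    block <- cc[ia, ib, drop = FALSE]
    v <- if (a == b) block[upper.tri(block)] else as.vector(block)
    out[a, b] <- out[b, a] <- mean(v, na.rm = TRUE)
  }
  structure(out, class = c("sound_correlation", "matrix"))
}

#' Cluster sounds from a correlation matrix (UPGMA + hybrid tree cut)
#'
#' Dissimilarity is 1 - correlation (anticorrelated sounds are far apart,
#' not close); the dendrogram uses unweighted average distance (UPGMA); the
#' hybrid dynamic tree cut with the given `deepsplit` defines the clusters.
#' Sounds assigned to no cluster are labelled `"unclustered"`.
#'
#' @param corr a `sound_correlation` matrix (diagonal = reliability)
#' @param deepsplit tree-cut sensitivity (default 2.5)
#' @param min_cluster minimum cluster size (default 2; the reference
#'   default of 20 exceeds the number of sounds presented)
#' @param include_unclustered_between include unclustered sounds in the
#'   between-cluster correlation (default FALSE)
#' @return object of class `cluster_result`: list with `labels` (integer,
#'   0 = unclustered, named by sound), `n_clusters`, `cluster_sizes`,
#'   `fraction_clustered`, `within_cor`, `between_cor`, `within_reliability`
#' @export
cluster_sounds <- function(corr, deepsplit = 2.5, min_cluster = 2,
                           include_unclustered_between = FALSE) {
  S <- nrow(corr)
  if (S < 3) stop("need at least 3 sounds to build a tree")
  if (!isTRUE(all.equal(unname(corr), unname(t(corr)), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  if (!all(is.finite(corr))) stop("correlation matrix must be finite")
  d <- 1 - corr
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- cutree_hybrid(hc, d, deep_split = deepsplit,
                          min_cluster_size = min_cluster)
  names(labels) <- rownames(corr)
  metrics <- cluster_metrics(corr, labels, include_unclustered_between)
  structure(c(list(labels = labels, dendrogram = hc), metrics),
            class = "cluster_result")
}

# within/between-cluster correlation and reliability for given labels
cluster_metrics <- function(corr, labels,
                            include_unclustered_between = FALSE) {
  S <- nrow(corr)
  ks <- sort(unique(labels[labels > 0]))
  off <- upper.tri(corr)
  same <- outer(labels, labels, "==") & outer(labels > 0, labels > 0, "&")
  clustered <- labels > 0
  if (include_unclustered_between) {
    between_mask <- off & !(same & off)
  } else {
    between_mask <- off & !same & outer(clustered, clustered, "&")
  }
  within_vals <- corr[same & off]
  between_vals <- corr[between_mask]
  list(n_clusters = length(ks),
       cluster_sizes = if (length(ks))
         as.integer(table(labels[labels > 0])) else integer(0),
       fraction_clustered = mean(clustered),
       within_cor = if (length(within_vals)) mean(within_vals) else NA_real_,
       between_cor = if (length(between_vals)) mean(between_vals)
       else NA_real_,
       within_reliability = if (any(clustered))
         mean(diag(corr)[clustered]) else NA_real_)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$n_clusters, "clusters (sizes",
      paste(x$cluster_sizes, collapse = ","), "),",
      sprintf("%.0f%% clustered; within r %.3f, between r %.3f, reliability %.3f\n",
              100 * x$fraction_clustered, x$within_cor, x$between_cor,
              x$within_reliability))
  invisible(x)
}

#' Cross-week cluster-content similarity
#'
#' For each week-1 cluster, the week-2 cluster sharing the largest fraction
#' of its sounds is its counterpart; the similarity of the field of view is
#' the mean, over week-1 clusters, of the fraction of sounds shared with
#' the counterpart. The fraction is |A intersect B| / |A| by default
#' (Jaccard selectable). Ties prefer the smaller week-2 cluster, then the
#' lowest label.
#'
#' @param week1,week2 `cluster_result` objects over the same sound set
#' @param method `"fraction"` (default) or `"jaccard"`
#' @return similarity in [0, 1]
#' @export
cross_week_cluster_similarity <- function(week1, week2,
                                          method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  l1 <- week1$labels; l2 <- week2$labels
  if (length(l1) != length(l2) ||
      (!is.null(names(l1)) && !is.null(names(l2)) &&
       !identical(names(l1), names(l2))))
    stop("cluster results are not over the same sound set")
  ks1 <- sort(unique(l1[l1 > 0]))
  ks2 <- sort(unique(l2[l2 > 0]))
  if (!length(ks1)) return(NA_real_)
  if (!length(ks2)) {
    warning("week 2 has no clusters; similarity 0")
    return(0)
  }
  per_cluster <- vapply(ks1, function(k) {
    A <- which(l1 == k)
    scores <- vapply(ks2, function(m) {
      B <- which(l2 == m)
      shared <- length(intersect(A, B))
      if (method == "fraction") shared / length(A)
      else shared / length(union(A, B))
    }, numeric(1))
    sizes2 <- vapply(ks2, function(m) sum(l2 == m), numeric(1))
    ord <- order(-scores, sizes2, ks2)
    scores[ord[1]]
  }, numeric(1))
  mean(per_cluster)
}

#' Cross-week matched-neuron correlation
#'
#' The two cell vectors of the same sound and repetition index, restricted
#' to matched neurons, are correlated (Pearson) for each sound and each
#' repetition present in both weeks (never between different sounds); the
#' mean over sounds and repetitions gives one value per field of view.
#'
#' @param week1,week2 `cell_vector_set` arrays (sound x rep x neuron) over
#'   the same sound set and matched neuron order
#' @param pairing `"same_rep"` (default, repetition i with repetition i) or
#'   `"all_pairs"`
#' @return mean Pearson r, or NA when fewer than 3 matched neurons
#' @export
cross_week_neuron_correlation <- function(week1, week2,
                                          pairing = c("same_rep",
                                                      "all_pairs")) {
  pairing <- match.arg(pairing)
  d1 <- dim(week1); d2 <- dim(week2)
  if (d1[1] != d2[1]) stop("sound sets differ")
  if (d1[3] != d2[3]) stop("matched neuron sets differ")
  if (d1[3] < 3) return(NA_real_)
  vals <- c()
  for (s in seq_len(d1[1])) {
    if (pairing == "same_rep") {
      for (r in seq_len(min(d1[2], d2[2]))) {
        v1 <- week1[s, r, ]; v2 <- week2[s, r, ]
        if (anyNA(v1) || anyNA(v2)) next
        if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
        vals <- c(vals, stats::cor(v1, v2))
      }
    } else {
      for (r1 in seq_len(d1[2])) for (r2 in seq_len(d2[2])) {
        v1 <- week1[s, r1, ]; v2 <- week2[s, r2, ]
        if (anyNA(v1) || anyNA(v2)) next
        if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
        vals <- c(vals, stats::cor(v1, v2))
      }
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
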