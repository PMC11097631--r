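# Hybrid dynamic tree cut: adaptive dendrogram cutting producing clusters
# of variable granularity, following the published Dynamic Hybrid
# algorithm (tree-based cluster detection followed by a PAM-like stage for
# leftover objects). Reimplemented here because no tree-cut package is
# available in the target environment.

# deepSplit in [0, 4] (fractional values allowed) is mapped onto the
# reference maximum-core-scatter defaults by linear interpolation;
# minGap = (1 - maxCoreScatter) * 3/4, both on a scale normalized between
# the 5th percentile of merge heights and the cut height.
.deepsplit_params <- function(deep_split) {
  if (deep_split < 0 || deep_split > 4)
    stop("'deep_split' must lie in [0, 4]")
  mcs_defaults <- c(0.64, 0.73, 0.82, 0.91, 0.95)
  mcs <- stats::approx(0:4, mcs_defaults, xout = deep_split)$y
  list(max_core_scatter = mcs, min_gap = (1 - mcs) * 3 / 4)
}

#' Cut a dendrogram with the hybrid dynamic tree cut
#'
#' Stage 1 walks the merges of the dendrogram bottom-up, growing branches
#' and deciding at every join whether each branch qualifies as a basic
#' cluster: it must (i) contain at least `min_cluster_size` objects,
#' (ii) have a core scatter (mean joining height of its core objects) below
#' a threshold, and (iii) be separated from its surroundings by a height
#' gap above a threshold. When two qualifying branches meet, both are
#' confirmed as clusters; a non-qualifying branch merging with a qualifying
#' one is absorbed. Merges above `cut_height` are ignored. Stage 2 (PAM
#' stage) assigns each leftover object to the cluster with the smallest
#' average dissimilarity, provided that distance does not exceed
#' `max_pam_dist`; remaining objects stay unassigned (label 0).
#'
#' The cluster-detection sensitivity `deep_split` follows the reference
#' 0-4 convention; fractional values (e.g. the 2.5 used for sound
#' clustering) interpolate between the integer presets.
#'
#' @param hc an [stats::hclust()] tree (typically UPGMA)
#' @param diss symmetric dissimilarity matrix the tree was built from
#' @param deep_split sensitivity in [0, 4] (default 2.5)
#' @param min_cluster_size minimum cluster size (default 2)
#' @param cut_height maximum merge height considered; default 0.99 * max
#'   height
#' @param pam_stage run the PAM-like assignment stage (default TRUE)
#' @param max_pam_dist maximum average dissimilarity for PAM assignment;
#'   `NULL` (default) uses a per-cluster limit — the cluster's core top
#'   plus the gap margin — so that an object is only attached if it sits
#'   about as close to the cluster as the cluster's own members do. (The
#'   reference default, the cut height itself, attaches even objects
#'   uncorrelated with every cluster when distances derive from
#'   correlations.)
#' @return integer label vector (0 = unassigned), ordered as the tree's
#'   leaves; clusters are numbered by decreasing size
#' @export
cutree_hybrid <- function(hc, diss, deep_split = 2.5, min_cluster_size = 2,
                          cut_height = NULL, pam_stage = TRUE,
                          max_pam_dist = NULL) {
  n <- length(hc$order)
  merge <- hc$merge
  height <- hc$height
  cut_height <- cut_height %||% (0.99 * max(height))
  pars <- .deepsplit_params(deep_split)
  ref_height <- as.numeric(stats::quantile(height, 0.05, names = FALSE))
  max_abs_scatter <- ref_height +
    pars$max_core_scatter * (cut_height - ref_height)
  min_abs_gap <- pars$min_gap * (cut_height - ref_height)

  # branch bookkeeping: members, the height each member joined, height of
  # the branch's last internal merge, composite flag
  branches <- list()
  new_branch <- function(members, join_h, last_h, composite = FALSE) {
    branches[[length(branches) + 1L]] <<-
      list(members = members, join_h = join_h, last_h = last_h,
           composite = composite)
    length(branches)
  }
  node_branch <- integer(nrow(merge))
  confirmed <- list()

  core_size <- function(sz) {
    min(sz, max(min_cluster_size,
                floor(min_cluster_size / 2 + 1) +
                  round(sqrt(max(sz - min_cluster_size / 2 - 1, 0)))))
  }
  core_top <- function(br) {
    max(sort(br$join_h)[seq_len(core_size(length(br$members)))])
  }
  is_basic <- function(br, h) {
    if (br$composite) return(FALSE)
    sz <- length(br$members)
    if (sz < min_cluster_size) return(FALSE)
    core_h <- sort(br$join_h)[seq_len(core_size(sz))]
    if (mean(core_h) > max_abs_scatter) return(FALSE)
    # gap: separation between the branch's attaching height and the height
    # at which its core completed (late stragglers do not shrink the gap)
    (h - max(core_h)) > min_abs_gap
  }
  # attachment margin: an outside object/branch may only be absorbed into a
  # qualifying branch if it joins within the gap margin of the branch core;
  # attachments farther out would erase the very gap that made the branch a
  # cluster
  within_margin <- function(br, h) h <= core_top(br) + min_abs_gap
  get_branch <- function(node, h) {
    if (node < 0) new_branch(-node, h, h) else node_branch[node]
  }

  stopped_at <- nrow(merge) + 1L
  for (i in seq_len(nrow(merge))) {
    h <- height[i]
    if (h > cut_height) { stopped_at <- i; break }
    bi <- get_branch(merge[i, 1], h)
    bj <- get_branch(merge[i, 2], h)
    b1 <- branches[[bi]]; b2 <- branches[[bj]]
    basic1 <- is_basic(b1, h); basic2 <- is_basic(b2, h)
    if (basic1 && basic2) {
      confirmed[[length(confirmed) + 1L]] <- list(members = b1$members,
                                                  core_top = core_top(b1))
      confirmed[[length(confirmed) + 1L]] <- list(members = b2$members,
                                                  core_top = core_top(b2))
      node_branch[i] <- new_branch(c(b1$members, b2$members),
                                   c(b1$join_h, b2$join_h), h,
                                   composite = TRUE)
    } else if (b1$composite || b2$composite) {
      # a basic branch meeting a composite is confirmed; a non-basic one
      # is left for the PAM stage
      if (basic1) confirmed[[length(confirmed) + 1L]] <-
        list(members = b1$members, core_top = core_top(b1))
      if (basic2) confirmed[[length(confirmed) + 1L]] <-
        list(members = b2$members, core_top = core_top(b2))
      node_branch[i] <- new_branch(c(b1$members, b2$members),
                                   c(b1$join_h, b2$join_h), h,
                                   composite = TRUE)
    } else if (basic1 != basic2) {
      winner <- if (basic1) b1 else b2
      loser <- if (basic1) b2 else b1
      if (within_margin(winner, h)) {
        # absorb the non-qualifying branch into the qualifying one
        node_branch[i] <- new_branch(
          c(winner$members, loser$members),
          c(winner$join_h, rep(h, length(loser$members))), h)
      } else {
        # too far out to absorb: the qualifying branch is confirmed, the
        # rest is left to the PAM stage
        confirmed[[length(confirmed) + 1L]] <-
          list(members = winner$members, core_top = core_top(winner))
        node_branch[i] <- new_branch(c(b1$members, b2$members),
                                     c(b1$join_h, b2$join_h), h,
                                     composite = TRUE)
      }
    } else {
      node_branch[i] <- new_branch(c(b1$members, b2$members),
                                   c(b1$join_h, b2$join_h), h)
    }
  }

  # surviving branches (not merged into any later branch) are evaluated at
  # the cut height; branches only grow by union, so branch k survives iff
  # no later branch contains its first member
  contained <- logical(length(branches))
  for (k in seq_along(branches)) {
    # a branch is contained if any later branch includes its first member
    # and is larger
    if (k < length(branches)) {
      m1 <- branches[[k]]$members[1]
      for (k2 in seq.int(k + 1L, length(branches))) {
        if (m1 %in% branches[[k2]]$members) { contained[k] <- TRUE; break }
      }
    }
  }
  for (k in which(!contained)) {
    br <- branches[[k]]
    if (is_basic(br, cut_height))
      confirmed[[length(confirmed) + 1L]] <-
        list(members = br$members, core_top = core_top(br))
  }

  # deduplicate confirmed clusters (a cluster may be confirmed twice) and
  # drop clusters that are strict subsets of other confirmed clusters
  if (length(confirmed)) {
    keys <- vapply(confirmed, function(cl)
      paste(sort(cl$members), collapse = ","), character(1))
    confirmed <- confirmed[!duplicated(keys)]
    keep <- rep(TRUE, length(confirmed))
    for (a in seq_along(confirmed)) for (b in seq_along(confirmed)) {
      if (a != b && keep[a] && keep[b] &&
          all(confirmed[[a]]$members %in% confirmed[[b]]$members) &&
          length(confirmed[[a]]$members) < length(confirmed[[b]]$members))
        keep[a] <- FALSE
    }
    confirmed <- confirmed[keep]
  }

  labels <- integer(n)
  for (k in seq_along(confirmed)) labels[confirmed[[k]]$members] <- k

  if (pam_stage && length(confirmed)) {
    diss <- as.matrix(diss)
    un <- which(labels == 0L)
    for (u in un) {
      dbar <- vapply(confirmed, function(cl)
        mean(diss[u, cl$members]), numeric(1))
      k_best <- which.min(dbar)
      limit <- max_pam_dist %||%
        (confirmed[[k_best]]$core_top + min_abs_gap)
      if (dbar[k_best] <= limit) labels[u] <- k_best
    }
  }

  # renumber by decreasing size
  if (any(labels > 0L)) {
    sizes <- table(labels[labels > 0L])
    ord <- names(sort(sizes, decreasing = TRUE))
    remap <- stats::setNames(seq_along(ord), ord)
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  labels
}
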