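# Global coordinates and local tonotopic heterogeneity (100 um IQR).

#' Convert FOV-local neuron positions to a global coordinate system
#'
#' @param neurons data.frame with `neuron_id`, `x`, `y`, `fov_id` (plus any
#'   other columns, e.g. `bf_khz`, `class`, carried through)
#' @param fov_offsets data.frame with `fov_id`, `dx`, `dy` (um), or a named
#'   list of c(dx, dy)
#' @return the input data.frame with `x`/`y` replaced by global coordinates
#'   (class `neuron_map`); within-FOV pairwise distances are preserved
#'   exactly
#' @export
to_global <- function(neurons, fov_offsets) {
  if (anyDuplicated(neurons$neuron_id))
    stop("duplicated neuron id(s): ",
         paste(unique(neurons$neuron_id[duplicated(neurons$neuron_id)]),
               collapse = ", "))
  if (is.list(fov_offsets) && !is.data.frame(fov_offsets)) {
    fov_offsets <- data.frame(fov_id = names(fov_offsets),
                              dx = vapply(fov_offsets, `[`, numeric(1), 1),
                              dy = vapply(fov_offsets, `[`, numeric(1), 2))
  }
  idx <- match(neurons$fov_id, fov_offsets$fov_id)
  if (anyNA(idx))
    stop("missing offset for FOV(s): ",
         paste(unique(neurons$fov_id[is.na(idx)]), collapse = ", "))
  out <- neurons
  out$x <- neurons$x + fov_offsets$dx[idx]
  out$y <- neurons$y + fov_offsets$dy[idx]
  class(out) <- c("neuron_map", class(out))
  out
}

#' Local best-frequency interquartile range (tonotopic heterogeneity)
#'
#' For each single-peak neuron, the best frequencies (octave scale) of all
#' single-peak neurons within `radius` um — including the neuron itself —
#' are collected and their interquartile range computed (linear-interpolation
#' quartiles, i.e. `stats::quantile` type 7). If fewer than `min_n` neurons
#' (including the centre) fall within the radius, no IQR is defined for that
#' neuron. Distances are Euclidean in the imaging plane; the radius is
#' inclusive.
#'
#' @param map a `neuron_map` data.frame with columns `x`, `y`, `bf_khz` (or
#'   `bf_oct`) and `class`
#' @param radius neighbourhood radius in um (default 100)
#' @param min_n minimum neighbourhood size (default 5)
#' @param scale `"oct"` (default) or `"khz"`
#' @param quantile_type passed to [stats::quantile()] (default 7)
#' @return data.frame: neuron_id, n_neighbors, iqr (NA when undefined)
#' @export
local_bf_iqr <- function(map, radius = 100, min_n = 5,
                         scale = c("oct", "khz"), quantile_type = 7) {
  scale <- match.arg(scale)
  if (radius <= 0) stop("'radius' must be > 0")
  sp <- map[map$class == "single", , drop = FALSE]
  bf <- if (scale == "oct") {
    if (!is.null(sp$bf_oct)) sp$bf_oct else khz_to_oct(sp$bf_khz)
  } else sp$bf_khz
  n <- nrow(sp)
  iqr <- rep(NA_real_, n)
  nn <- integer(n)
  if (n) {
    for (i in seq_len(n)) {
      d2 <- (sp$x - sp$x[i])^2 + (sp$y - sp$y[i])^2
      nb <- which(d2 <= radius^2)
      nn[i] <- length(nb)
      if (length(nb) >= min_n) {
        q <- stats::quantile(bf[nb], c(0.25, 0.75), type = quantile_type,
                             names = FALSE)
        iqr[i] <- q[2] - q[1]
      }
    }
  }
  data.frame(neuron_id = sp$neuron_id, n_neighbors = nn, iqr = iqr,
             stringsAsFactors = FALSE)
}

#' Best-frequency band fractions per subfield
#'
#' Fractions of single-peak neurons whose BF falls into each named band, per
#' subfield. The default bands are low (4 to <6 kHz), mid (6-17 kHz) and
#' high (24-64 kHz); grid tones between 17 and 24 kHz belong to no named
#' band and are reported as `other` rather than silently merged. Empty
#' subfields are reported as missing (NA), not 0.
#'
#' @param map a `neuron_map` with columns `bf_khz`, `class`, `subfield`
#' @param bands data.frame with `name`, `lo`, `hi` (inclusive bounds except
#'   where noted); must not overlap
#' @return data.frame: subfield, band, n, fraction
#' @export
bf_distribution <- function(map, bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(name = c("low", "mid", "high"),
                        lo = c(4, 6, 24), hi = c(6 - 1e-9, 17, 64))
  o <- order(bands$lo)
  bands <- bands[o, ]
  if (any(bands$hi[-nrow(bands)] > bands$lo[-1]))
    stop("bands overlap")
  sp <- map[map$class == "single", , drop = FALSE]
  if (is.null(sp$subfield)) sp$subfield <- "unassigned"
  band_of <- function(bf) {
    hit <- which(bf >= bands$lo & bf <= bands$hi)
    if (length(hit)) bands$name[hit[1]] else "other"
  }
  sp$band <- vapply(sp$bf_khz, band_of, character(1))
  out <- do.call(rbind, lapply(split(sp, sp$subfield), function(d) {
    lv <- c(bands$name, "other")
    cnt <- table(factor(d$band, levels = lv))
    data.frame(subfield = d$subfield[1], band = lv, n = as.integer(cnt),
               fraction = if (nrow(d)) as.numeric(cnt) / nrow(d) else
                 NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
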