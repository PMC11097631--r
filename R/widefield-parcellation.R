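# Reversal-point detection by radial scanning, AC boundary, and subfield
# parcellation of the widefield best-frequency map.

# 3x3 median filter with edge replication
median_filter3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, 1:H, H), c(1, 1:W, W)]
  stack <- vapply(1:9, function(k) {
    di <- (k - 1) %% 3; dj <- (k - 1) %/% 3
    as.numeric(pad[di + 1:H, dj + 1:W])
  }, numeric(H * W))
  matrix(apply(stack, 1, stats::median, na.rm = TRUE), H, W)
}

# connected components (4-neighbourhood) of a logical matrix; returns an
# integer label matrix (0 = background)
connected_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (q in c(if (i > 1) p - 1L, if (i < H) p + 1L,
                  if (j > 1) p - H, if (j < W) p + H)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Detect low-frequency hub centres in a best-frequency map
#'
#' The lowest-BF quintile of responsive pixels (after 3x3 median filtering
#' of the octave-scale map) is segmented into connected components; the
#' centroid of each sufficiently large component is a hub centre.
#'
#' @param map a `pixel_bf_map`
#' @param quantile quantile defining "low frequency" (default 0.2)
#' @param min_size minimum component size in pixels (default 25)
#' @return list of c(x, y) hub centres (column, row)
#' @export
find_hubs <- function(map, quantile = 0.2, min_size = 25) {
  bf_oct <- khz_to_oct(map$bf_khz)
  sm <- median_filter3(bf_oct)
  thr <- stats::quantile(sm[map$responsive], quantile, na.rm = TRUE)
  mask <- !is.na(sm) & sm <= thr & map$responsive
  lab <- connected_components(mask)
  sizes <- tabulate(lab)
  cand <- which(sizes >= min_size)
  # the true hub contains the lowest BFs; rank components by their minimum
  cand <- cand[order(vapply(cand, function(k) min(sm[lab == k]),
                            numeric(1)))]
  hubs <- lapply(cand, function(k) {
    idx <- which(lab == k)
    i <- (idx - 1) %% nrow(lab) + 1; j <- (idx - 1) %/% nrow(lab) + 1
    c(x = mean(j), y = mean(i))
  })
  if (!length(hubs)) stop("no low-frequency hub found")
  hubs
}

# sum-of-three-Gaussians fit of a radial profile; returns fitted values on
# the same radius grid (NULL if the fit fails)
fit_gauss3 <- function(r, y) {
  ok <- is.finite(y)
  if (sum(ok) < 12) return(NULL)
  rr <- r[ok]; yy <- y[ok]
  model <- function(p) {
    p[1] * exp(-((rr - p[2]) / p[3])^2) +
      p[4] * exp(-((rr - p[5]) / p[6])^2) +
      p[7] * exp(-((rr - p[8]) / p[9])^2)
  }
  obj <- function(p) sum((model(p) - yy)^2)
  a0 <- max(yy); span <- diff(range(rr)) + 1
  pk <- rr[which.max(yy)]
  start <- c(a0, pk, span / 4,
             a0 / 2, rr[1] + span / 4, span / 3,
             a0 / 2, rr[length(rr)] - span / 4, span / 3)
  lower <- c(0, min(rr) - span / 2, 1, 0, min(rr) - span / 2, 1,
             0, min(rr) - span / 2, 1)
  upper <- c(2 * a0 + 1e-6, max(rr) + span / 2, span,
             2 * a0 + 1e-6, max(rr) + span / 2, span,
             2 * a0 + 1e-6, max(rr) + span / 2, span)
  fit <- tryCatch(stats::optim(clamp(start, lower, upper), obj,
                               method = "L-BFGS-B", lower = lower,
                               upper = upper, control = list(maxit = 200)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  out <- rep(NA_real_, length(r))
  f_all <- p[1] * exp(-((r - p[2]) / p[3])^2) +
    p[4] * exp(-((r - p[5]) / p[6])^2) +
    p[7] * exp(-((r - p[8]) / p[9])^2)
  out[] <- f_all
  out
}

# first interior local maximum of a (possibly NA-bearing) profile; a
# plateau only counts when a strictly lower value follows it (a monotone
# staircase has no maximum); returns the plateau centre
first_local_max <- function(y) {
  ok <- which(is.finite(y))
  if (length(ok) < 3) return(NA_integer_)
  v <- y[ok]
  n <- length(v)
  i <- 2L
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1L
      if (j < n && v[j + 1] < v[i]) return(ok[floor((i + j) / 2)])
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_integer_
}

#' Radial reversal points and the auditory-cortex boundary
#'
#' From each hub centre, 1,440 radial directions (0.25 degree steps) are
#' scanned. Along each direction, octave-scale BFs of responsive pixels
#' within +-1 degree are averaged in 1-pixel radial bins, smoothed with a
#' 10-sample moving average, and (by default) fitted with a sum of three
#' Gaussians over radius; the first local maximum of the fitted profile is
#' the reversal point for that direction. Independently, the AC end along a
#' direction is marked where `silent_run` consecutive radial bins contain
#' pixels but none of them responsive. Directions with fewer than 10
#' responsive radial samples report no reversal.
#'
#' @param map a `pixel_bf_map`
#' @param hubs list of c(x, y) hub centres; `NULL` = [find_hubs()]
#' @param n_dir number of radial directions (default 1440)
#' @param half_angle_deg half-width of the angular wedge (default 1)
#' @param ma_window moving-average window in radial samples (default 10)
#' @param fit `"gauss3"` (sum-of-three-Gaussians fit, default) or
#'   `"smooth"` (use the moving-averaged profile directly)
#' @param silent_run consecutive non-responsive bins defining the AC end
#'   (default 10)
#' @return object of class `parcellation_result`: list with `hubs`,
#'   `reversals` (data.frame direction_deg, radius, x, y), `boundary`
#'   (same layout)
#' @export
find_reversals_and_boundary <- function(map, hubs = NULL, n_dir = 1440,
                                        half_angle_deg = 1, ma_window = 10,
                                        fit = c("gauss3", "smooth"),
                                        silent_run = 10) {
  fit <- match.arg(fit)
  if (is.null(hubs)) hubs <- find_hubs(map)
  if (!length(hubs)) stop("at least one hub centre is required")
  H <- map$height; W <- map$width
  bf_oct <- khz_to_oct(map$bf_khz)
  px_x <- rep(seq_len(W), each = H)
  px_y <- rep(seq_len(H), times = W)
  resp <- as.vector(map$responsive)
  bfv <- as.vector(bf_oct)
  ma <- rep(1 / ma_window, ma_window)

  rev_list <- list(); bnd_list <- list()
  for (hub in hubs) {
    dx <- px_x - hub[1]; dy <- px_y - hub[2]
    r <- sqrt(dx^2 + dy^2)
    theta <- (atan2(dy, dx) * 180 / pi) %% 360
    ord <- order(theta)
    th_s <- theta[ord]; r_s <- r[ord]; resp_s <- resp[ord]; bf_s <- bfv[ord]
    dirs <- (seq_len(n_dir) - 1) * 360 / n_dir
    for (k in seq_len(n_dir)) {
      th0 <- dirs[k]
      lo <- th0 - half_angle_deg; hi <- th0 + half_angle_deg
      if (lo < 0) {
        sel <- c(which(th_s >= lo + 360), which(th_s <= hi))
      } else if (hi > 360) {
        sel <- c(which(th_s >= lo), which(th_s <= hi - 360))
      } else {
        i1 <- findInterval(lo, th_s) + 1L
        i2 <- findInterval(hi, th_s)
        sel <- if (i2 >= i1) i1:i2 else integer(0)
      }
      # exact-ray samples: nearest pixel at every 1-px radial step (the
      # angular wedge is too thin to contain pixel centres at small radii)
      ray_max <- 0L
      cs <- cos(th0 * pi / 180); sn <- sin(th0 * pi / 180)
      repeat {
        xr <- round(hub[1] + (ray_max + 1L) * cs)
        yr <- round(hub[2] + (ray_max + 1L) * sn)
        if (xr < 1 || xr > W || yr < 1 || yr > H) break
        ray_max <- ray_max + 1L
      }
      if (ray_max < 3) next
      xr <- pmin(pmax(round(hub[1] + seq_len(ray_max) * cs), 1L), W)
      yr <- pmin(pmax(round(hub[2] + seq_len(ray_max) * sn), 1L), H)
      ray_idx <- (xr - 1L) * H + yr
      ray_resp <- resp[ray_idx]
      ray_bf <- bfv[ray_idx]
      rmax <- ray_max
      prof <- ifelse(ray_resp, ray_bf, NA_real_)
      # overlay wedge means where the +-1 degree wedge has responsive pixels
      if (length(sel)) {
        rb <- pmax(round(r_s[sel]), 1L)
        keep <- rb <= rmax
        rb <- rb[keep]
        rsel <- resp_s[sel][keep]
        if (any(rsel)) {
          agg <- rowsum(bf_s[sel][keep][rsel], rb[rsel])
          cnt <- rowsum(rep(1, sum(rsel)), rb[rsel])
          at <- as.integer(rownames(agg))
          prof[at] <- agg[, 1] / cnt[, 1]
        }
      }

      # AC boundary: first run of silent_run consecutive ray samples with
      # no sound-evoked response at all
      silent <- !ray_resp
      run <- 0L; b_at <- NA_integer_
      for (i in seq_len(rmax)) {
        if (silent[i]) {
          run <- run + 1L
          if (run >= silent_run) { b_at <- i - silent_run + 1L; break }
        } else run <- 0L
      }
      if (!is.na(b_at))
        bnd_list[[length(bnd_list) + 1L]] <-
          c(th0, b_at, hub[1] + b_at * cos(th0 * pi / 180),
            hub[2] + b_at * sin(th0 * pi / 180))

      if (sum(is.finite(prof)) < 10) next
      # thin wedges leave empty radial bins; interpolate interior gaps so
      # the moving average does not propagate them
      fin <- which(is.finite(prof))
      prof_i <- prof
      gaps <- setdiff(seq(min(fin), max(fin)), fin)
      if (length(gaps))
        prof_i[gaps] <- stats::approx(fin, prof[fin], xout = gaps)$y
      prof_sm <- as.numeric(stats::filter(prof_i, ma, sides = 2))
      curve <- if (fit == "gauss3") {
        fg <- fit_gauss3(seq_len(rmax), prof_sm)
        if (is.null(fg)) prof_sm else fg
      } else prof_sm
      # restrict the search to radii inside the responsive extent
      last_resp <- max(which(is.finite(prof)))
      curve[seq_len(rmax) > last_resp] <- NA_real_
      i_max <- first_local_max(curve)
      if (!is.na(i_max))
        rev_list[[length(rev_list) + 1L]] <-
          c(th0, i_max, hub[1] + i_max * cos(th0 * pi / 180),
            hub[2] + i_max * sin(th0 * pi / 180))
    }
  }
  as_df <- function(lst) {
    if (!length(lst))
      return(data.frame(direction_deg = numeric(0), radius = numeric(0),
                        x = numeric(0), y = numeric(0)))
    d <- as.data.frame(do.call(rbind, lst))
    names(d) <- c("direction_deg", "radius", "x", "y")
    d
  }
  structure(list(hubs = hubs, reversals = as_df(rev_list),
                 boundary = as_df(bnd_list)),
            class = "parcellation_result")
}

# ray-casting point-in-polygon; poly is a data.frame/matrix with x, y
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Parcellate the widefield map into subfields
#'
#' Mode `"import"` applies externally supplied closed border polygons (the
#' manual drawing step of the original workflow): each responsive pixel is
#' labelled by the first polygon containing it. Mode `"auto"` connects the
#' detected reversal points into a closed border by angular ordering and
#' assigns labels by position relative to the low-frequency hub — inside
#' the reversal border and posterior of the hub is A1, inside and anterior
#' is AAF, outside is A2. The auto mode is an explicit heuristic
#' approximation and its output is labelled as such.
#'
#' @param map a `pixel_bf_map`
#' @param result a `parcellation_result` (required for `"auto"`)
#' @param mode `"auto"` or `"import"`
#' @param borders named list of closed polygons (data.frames with `x`, `y`)
#'   for `"import"`
#' @return list with `labels` (character matrix H x W: `"A1"`, `"AAF"`,
#'   `"A2"`, `"unassigned"`, `"none"`), `border` (the polygon used, auto
#'   mode), and `mode`
#' @export
parcellate <- function(map, result = NULL, mode = c("auto", "import"),
                       borders = NULL) {
  mode <- match.arg(mode)
  H <- map$height; W <- map$width
  labels <- matrix("none", H, W)
  px_x <- rep(seq_len(W), each = H)
  px_y <- rep(seq_len(H), times = W)
  resp <- as.vector(map$responsive)
  if (mode == "import") {
    if (is.null(borders) || !length(borders)) stop("no borders supplied")
    for (nm in names(borders)) {
      b <- as.matrix(borders[[nm]][, c("x", "y")])
      if (any(b[1, ] != b[nrow(b), ]))
        stop("border '", nm, "' is not closed")
      inside <- point_in_polygon(px_x, px_y, b)
      lab <- as.vector(labels)
      lab[inside & lab == "none"] <- nm
      labels <- matrix(lab, H, W)
    }
    return(list(labels = labels, border = NULL, mode = mode))
  }
  if (is.null(result)) stop("'result' is required for auto mode")
  rv <- result$reversals
  lab <- as.vector(labels)
  if (nrow(rv) < 3) {
    lab[resp] <- "unassigned"
    return(list(labels = matrix(lab, H, W), border = NULL, mode = mode,
                note = "no reversal border found; heuristic auto mode"))
  }
  rv <- rv[order(rv$direction_deg), ]
  border <- rbind(as.matrix(rv[, c("x", "y")]),
                  as.matrix(rv[1, c("x", "y")]))
  hub <- result$hubs[[1]]
  inside <- point_in_polygon(px_x, px_y, border)
  lab[resp & inside & px_x >= hub[1]] <- "A1"
  lab[resp & inside & px_x < hub[1]] <- "AAF"
  lab[resp & !inside] <- "A2"
  list(labels = matrix(lab, H, W), border = border, mode = mode,
       note = "auto mode: heuristic assignment relative to the hub")
}
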