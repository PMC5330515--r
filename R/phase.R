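# Phase computation, phase-singularity (PS) detection by topological charge,
# and greedy PS trajectory tracking.

wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Compute the phase of voltage maps
#'
#' Default method is time-delay embedding:
#' `phase = atan2(V(t - tau) - Vbar, V(t) - Vbar)` with the per-node mean
#' `Vbar` taken over a sliding window (or globally). An analytic-signal
#' (Hilbert transform) alternative is available.
#'
#' @param maps numeric matrix, nodes x time samples.
#' @param times sample times (ms), uniformly spaced.
#' @param tau embedding delay (ms, default 10).
#' @param method `"delay"` or `"hilbert"`.
#' @param mean_window width (ms) of the sliding window for `Vbar`
#'   (`Inf` = global mean).
#' @return List with `phase` (nodes x n_out matrix, values in (-pi, pi]),
#'   `times` (the time points of the phase samples) and `valid` (logical per
#'   node; `FALSE` where the signal has no amplitude, e.g. constant traces).
#' @export
compute_phase <- function(maps, times, tau = 10, method = c("delay", "hilbert"),
                          mean_window = 1000) {
  method <- match.arg(method)
  maps <- as.matrix(maps)
  nt <- ncol(maps)
  stopifnot(length(times) == nt, nt >= 3)
  dt <- times[2] - times[1]
  amp <- apply(maps, 1, function(x) diff(range(x)))
  valid <- amp > 1e-6
  vbar <- if (is.finite(mean_window)) {
    k <- max(1L, round(mean_window / dt))
    if (k %% 2 == 0) k <- k + 1L
    kern <- rep(1 / k, k)
    t(apply(maps, 1, function(x) {
      f <- stats::filter(x, kern, sides = 2)
      # pad the window edges with the nearest full-window value
      f <- as.numeric(f)
      first <- which(!is.na(f))[1]
      last <- tail(which(!is.na(f)), 1)
      f[seq_len(first - 1)] <- f[first]
      f[seq(last + 1, length.out = length(f) - last)] <- f[last]
      f
    }))
  } else {
    matrix(rowMeans(maps), nrow(maps), nt)
  }
  if (method == "delay") {
    lag <- max(1L, round(tau / dt))
    idx <- (lag + 1):nt
    ph <- atan2(maps[, idx - lag, drop = FALSE] - vbar[, idx, drop = FALSE],
                maps[, idx, drop = FALSE] - vbar[, idx, drop = FALSE])
    out_t <- times[idx]
  } else {
    ctr <- maps - vbar
    ph <- t(apply(ctr, 1, function(x) {
      n <- length(x)
      X <- fft(x)
      h <- numeric(n); h[1] <- 1
      if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
      else h[2:((n + 1) / 2)] <- 2
      z <- fft(X * h, inverse = TRUE) / n
      atan2(Im(z), Re(z))
    }))
    out_t <- times
  }
  ph[!valid, ] <- NA_real_
  list(phase = ph, times = out_t, valid = valid)
}

#' Detect phase singularities in one phase frame
#'
#' Topological-charge detection: the closed-loop sum of wrapped phase
#' differences around each elementary plaquette (grid) or triangle (mesh)
#' equals +-2*pi at a singularity and 0 elsewhere.
#'
#' @param phase for a grid: an nx x ny matrix of phases; for a mesh: a
#'   vector of per-vertex phases.
#' @param domain optional `tissue_domain`/`la_geometry` for meshes (required
#'   to supply triangles and coordinates) or a grid `tissue_domain` to get
#'   physical coordinates.
#' @param exclude_boundary for meshes, drop triangles touching boundary
#'   vertices (default `TRUE`).
#' @return Data frame with columns `x`, `y` (and `z` for meshes), `chirality`
#'   (+1/-1) and `cell` (plaquette or triangle index).
#' @export
detect_phase_singularities <- function(phase, domain = NULL,
                                       exclude_boundary = TRUE) {
  if (is.matrix(phase)) {
    nx <- nrow(phase); ny <- ncol(phase)
    p00 <- phase[-nx, -ny]; p10 <- phase[-1, -ny]
    p11 <- phase[-1, -1]; p01 <- phase[-nx, -1]
    s <- wrap_pi(p10 - p00) + wrap_pi(p11 - p10) +
      wrap_pi(p01 - p11) + wrap_pi(p00 - p01)
    q <- round(s / (2 * pi))
    hit <- which(q != 0, arr.ind = TRUE)
    dx <- if (!is.null(domain)) domain$dx else 1
    out <- data.frame(x = (hit[, 1] - 0.5) * dx, y = (hit[, 2] - 0.5) * dx,
                      chirality = q[hit],
                      cell = hit[, 1] + (hit[, 2] - 1) * (nx - 1))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(!is.null(domain))
  tri <- if (!is.null(domain$tri)) domain$tri else domain$triangles
  vtx <- if (!is.null(domain$coords)) domain$coords else domain$vertices
  keep <- rep(TRUE, nrow(tri))
  if (exclude_boundary) {
    bl <- mesh_boundary_loops(tri)
    bv <- unlist(bl)
    if (length(bv))
      keep <- !(tri[, 1] %in% bv | tri[, 2] %in% bv | tri[, 3] %in% bv)
  }
  pa <- phase[tri[, 1]]; pb <- phase[tri[, 2]]; pc <- phase[tri[, 3]]
  s <- wrap_pi(pb - pa) + wrap_pi(pc - pb) + wrap_pi(pa - pc)
  q <- round(s / (2 * pi))
  q[!keep | is.na(q)] <- 0L
  hit <- which(q != 0)
  cent <- (vtx[tri[hit, 1], , drop = FALSE] + vtx[tri[hit, 2], , drop = FALSE] +
             vtx[tri[hit, 3], , drop = FALSE]) / 3
  out <- data.frame(x = cent[, 1], y = cent[, 2],
                    z = if (ncol(vtx) >= 3) cent[, 3] else 0,
                    chirality = q[hit], cell = hit)
  rownames(out) <- NULL
  out
}

#' Detect phase singularities in every frame
#'
#' @param phase_maps nodes x time phase matrix (mesh) or a 3D array
#'   nx x ny x time (grid).
#' @param times frame times (ms).
#' @param domain as in [detect_phase_singularities()].
#' @param ... passed to [detect_phase_singularities()].
#' @return Data frame of detections with `frame` and `time` columns.
#' @export
detect_ps_series <- function(phase_maps, times, domain = NULL, ...) {
  nt <- length(times)
  res <- vector("list", nt)
  for (f in seq_len(nt)) {
    ph <- if (length(dim(phase_maps)) == 3) phase_maps[, , f] else
      phase_maps[, f]
    d <- detect_phase_singularities(ph, domain, ...)
    if (nrow(d)) { d$frame <- f; d$time <- times[f]; res[[f]] <- d }
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), chirality = integer(0),
                      cell = integer(0), frame = integer(0),
                      time = numeric(0))
  out
}

#' Track phase singularities over time
#'
#' Greedy nearest-neighbour frame-to-frame linking: a detection continues an
#' existing track if it lies within `max_hop` of the track's last position
#' and the gap is at most `max_gap` frames; otherwise it starts a new track.
#'
#' @param detections data frame from [detect_ps_series()].
#' @param max_hop maximal spatial hop between consecutive detections (mm).
#' @param max_gap maximal number of missed frames inside a track.
#' @return List with `tracks` (list of data frames, each a `ps_track` with
#'   chirality and trajectory) and `summary` (count, mean and SD lifespan in
#'   ms).
#' @export
track_ps <- function(detections, max_hop = 2, max_gap = 2) {
  tracks <- list()
  open_last <- list()  # per open track: list(idx, frame, x, y, z, chir)
  coords <- function(d) c(d$x, d$y, if (!is.null(d$z)) d$z else 0)
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    # close stale tracks
    if (length(open_last)) {
      stale <- vapply(open_last, function(o) f - o$frame > max_gap + 1,
                      logical(1))
      open_last <- open_last[!stale]
    }
    # match open tracks to nearest same-chirality detection
    if (length(open_last)) {
      for (oi in seq_along(open_last)) {
        o <- open_last[[oi]]
        cand <- which(!used & det$chirality == o$chir)
        if (!length(cand)) next
        dists <- sqrt((det$x[cand] - o$x)^2 + (det$y[cand] - o$y)^2 +
                        (if (!is.null(det$z)) (det$z[cand] - o$z)^2 else 0))
        j <- cand[which.min(dists)]
        if (min(dists) <= max_hop) {
          used[j] <- TRUE
          tracks[[o$idx]] <- rbind(tracks[[o$idx]], det[j, ])
          open_last[[oi]]$frame <- f
          open_last[[oi]]$x <- det$x[j]; open_last[[oi]]$y <- det$y[j]
          open_last[[oi]]$z <- if (!is.null(det$z)) det$z[j] else 0
        }
      }
    }
    for (j in which(!used)) {
      tracks[[length(tracks) + 1]] <- det[j, , drop = FALSE]
      open_last[[length(open_last) + 1]] <-
        list(idx = length(tracks), frame = f, x = det$x[j], y = det$y[j],
             z = if (!is.null(det$z)) det$z[j] else 0,
             chir = det$chirality[j])
    }
  }
  lifespans <- vapply(tracks, function(tr) max(tr$time) - min(tr$time),
                      numeric(1))
  list(tracks = tracks,
       summary = list(count = length(tracks),
                      mean_lifespan = if (length(lifespans)) mean(lifespans) else NA_real_,
                      sd_lifespan = if (length(lifespans) > 1) sd(lifespans) else NA_real_,
                      total_detections = nrow(detections)))
}
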