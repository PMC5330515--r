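# Tissue domains (2D finite-difference sheet, triangulated surface mesh),
# diffusion operators and the monodomain run wrapper around the compiled
# kernel.

#' Default isotropic diffusion coefficient
#'
#' Calibrated so that a planar wave on the 250-um sheet conducts at roughly
#' 0.4-0.5 m/s (physiological atrial range). See [measure_planar_cv()] for
#' the calibration utility.
#'
#' @return Diffusion coefficient in mm^2/ms.
#' @export
default_diffusion <- function() 0.1

#' Create a 2D rectangular sheet domain
#'
#' @param nx,ny number of nodes in each direction.
#' @param dx node spacing in um (default 250).
#' @param D diffusion coefficient (mm^2/ms).
#' @return A `tissue_domain` object (type `"grid"`). Nodes are indexed
#'   column-major: node = ix + (iy-1)*nx.
#' @export
tissue_grid <- function(nx = 20, ny = 20, dx = 250, D = default_diffusion()) {
  if (dx <= 0) stop("dx must be > 0")
  n <- nx * ny
  ix <- rep(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  dom <- list(type = "grid", nx = nx, ny = ny, dx = dx / 1000, n = n,
              coords = cbind(x = (ix - 1) * dx / 1000, y = (iy - 1) * dx / 1000),
              D = D,
              vidx = rep(1L, n), variants = list(model_variant()),
              ach = rep(0, n), lesion = rep(FALSE, n))
  class(dom) <- "tissue_domain"
  dom
}

#' Create a triangulated-surface domain
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices with
#'   consistent orientation.
#' @param D diffusion coefficient (mm^2/ms).
#' @return A `tissue_domain` object (type `"mesh"`).
#' @export
tissue_mesh <- function(vertices, triangles, D = default_diffusion()) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  n <- nrow(vertices)
  if (max(triangles) > n || min(triangles) < 1)
    stop("triangle indices out of range")
  dom <- list(type = "mesh", n = n, coords = vertices, tri = triangles,
              D = D, vidx = rep(1L, n), variants = list(model_variant()),
              ach = rep(0, n), lesion = rep(FALSE, n))
  class(dom) <- "tissue_domain"
  dom
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat("<tissue_domain> ", x$type, ", ", x$n, " nodes",
      if (x$type == "grid") paste0(" (", x$nx, "x", x$ny, ", dx = ",
                                   x$dx * 1000, " um)"),
      ", D = ", x$D, " mm^2/ms, ", sum(x$lesion), " lesioned\n", sep = "")
  invisible(x)
}

#' Assign model variants to nodes
#'
#' @param domain a `tissue_domain`.
#' @param variants list of [model_variant()] objects.
#' @param vidx integer vector (length n) mapping each node to an entry of
#'   `variants`; default all nodes to the first variant.
#' @return The updated domain.
#' @export
set_variants <- function(domain, variants, vidx = NULL) {
  if (inherits(variants, "model_variant")) variants <- list(variants)
  if (is.null(vidx)) vidx <- rep(1L, domain$n)
  stopifnot(length(vidx) == domain$n, all(vidx >= 1), all(vidx <= length(variants)))
  domain$variants <- variants
  domain$vidx <- as.integer(vidx)
  # default per-node ACh from the variant field
  domain$ach <- vapply(variants, `[[`, numeric(1), "ACh")[vidx]
  domain
}

#' Set the per-node acetylcholine field
#'
#' Overrides any ACh carried by the node variants (used by the GP layout).
#'
#' @param domain a `tissue_domain`.
#' @param ach numeric vector (length n), uM, >= 0.
#' @return The updated domain.
#' @export
set_ach_field <- function(domain, ach) {
  stopifnot(length(ach) == domain$n, all(ach >= 0))
  domain$ach <- as.numeric(ach)
  domain
}

#' Add lesioned (ablated) nodes
#'
#' Lesioned nodes are non-excitable and excluded from the diffusion stencil
#' (no-flux boundary around the lesion).
#'
#' @param domain a `tissue_domain`.
#' @param nodes integer node indices.
#' @return The updated domain.
#' @export
add_lesion <- function(domain, nodes) {
  domain$lesion[nodes] <- TRUE
  domain
}

# mesh helpers -------------------------------------------------------------

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex lumped areas of a mesh domain (barycentric thirds)
#' @param domain a mesh `tissue_domain`.
#' @return Numeric vector of vertex areas (mm^2).
#' @export
vertex_areas <- function(domain) {
  stopifnot(domain$type == "mesh")
  ar <- triangle_areas(domain$coords, domain$tri)
  va <- numeric(domain$n)
  for (k in 1:3) {
    s <- tapply(rep(ar / 3, 1), domain$tri[, k], sum)
    va[as.integer(names(s))] <- va[as.integer(names(s))] + s
  }
  va
}

#' Build the diffusion operator of a domain
#'
#' Grid domains use the standard 5-point Laplacian with no-flux boundaries;
#' mesh domains use cotangent weights with barycentric area lumping (or a
#' uniform graph Laplacian as a robustness fallback). Lesioned nodes
#' contribute no flux: their rows and columns are removed from the stencil
#' and neighbouring diagonals adjusted so interior row sums stay zero.
#'
#' @param domain a `tissue_domain`.
#' @param method mesh weighting: `"cotan"` (default) or `"graph"`.
#' @return A sparse `dgCMatrix` (n x n) in units of 1/ms (D included).
#' @export
build_diffusion_operator <- function(domain, method = c("cotan", "graph")) {
  method <- match.arg(method)
  n <- domain$n
  if (domain$type == "grid") {
    nx <- domain$nx; ny <- domain$ny
    idx <- function(ix, iy) ix + (iy - 1L) * nx
    ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
    ii <- integer(0); jj <- integer(0)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
      ii <- c(ii, idx(ix[ok], iy[ok])); jj <- c(jj, idx(jx[ok], jy[ok]))
    }
    w <- rep(1, length(ii))
    scale_row <- rep(domain$D / domain$dx^2, n)
  } else {
    tri <- domain$tri; vtx <- domain$coords
    cot3 <- function(p, q, r) {
      # cotangent of angle at p in triangle (p, q, r)
      u <- q - p; v <- r - p
      cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
              u[1] * v[2] - u[2] * v[1])
      nc <- sqrt(sum(cr^2))
      if (nc < 1e-12) stop("degenerate triangle encountered")
      sum(u * v) / nc
    }
    ar <- triangle_areas(vtx, tri)
    if (any(ar < 1e-10))
      stop("degenerate (zero-area) triangles at indices: ",
           paste(which(ar < 1e-10), collapse = ", "))
    m <- nrow(tri)
    ii <- integer(0); jj <- integer(0); w <- numeric(0)
    if (method == "cotan") {
      for (corner in 1:3) {
        p <- tri[, corner]
        q <- tri[, corner %% 3 + 1]
        r <- tri[, (corner + 1) %% 3 + 1]
        ct <- vapply(seq_len(m), function(t)
          cot3(vtx[p[t], ], vtx[q[t], ], vtx[r[t], ]), numeric(1))
        ct <- pmax(ct, 0)  # clamp obtuse contributions for robustness
        # angle at p weights the opposite edge (q, r)
        ii <- c(ii, q, r); jj <- c(jj, r, q); w <- c(w, ct / 2, ct / 2)
      }
    } else {
      e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
      l2 <- rowSums((vtx[e[, 1], ] - vtx[e[, 2], ])^2)
      ii <- c(e[, 1], e[, 2]); jj <- c(e[, 2], e[, 1])
      w <- rep(1 / l2, 2) * mean(l2)  # dimensionless, unit mean weight
      # each undirected edge appears twice across triangles on interior; the
      # sparse constructor below sums duplicates, harmless for the fallback
    }
    va <- vertex_areas(domain)
    scale_row <- domain$D / va
    if (method == "graph") scale_row <- rep(domain$D / mean(l2), n)
  }
  keep <- !domain$lesion[ii] & !domain$lesion[jj]
  W <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = w[keep],
                            dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2  # symmetrize (sums duplicates first)
  L <- W - Matrix::Diagonal(n, Matrix::rowSums(W))
  Matrix::Diagonal(n, scale_row) %*% L
}

# convert dgCMatrix to CSR triplet for the kernel
.csr_parts <- function(L) {
  Lt <- Matrix::t(L)  # column-compressed transpose = CSR of L
  Lt <- methods::as(methods::as(Lt, "generalMatrix"), "CsparseMatrix")
  list(p = Lt@p, j = Lt@i, x = Lt@x)
}

#' Define a stimulus train
#'
#' @param nodes integer node indices receiving the pulse.
#' @param start time of the first pulse (ms).
#' @param period pacing cycle length (ms).
#' @param count number of pulses.
#' @param dur pulse width (ms, default 2).
#' @param amp pulse amplitude in pA/pF (negative = depolarizing; default
#'   -40, about twice diastolic threshold).
#' @return A `stim_train` list.
#' @export
stim_train <- function(nodes, start = 0, period = 1000, count = 1,
                       dur = 2, amp = -40) {
  stopifnot(length(nodes) >= 1, period > 0, count >= 1, dur > 0, dur <= period)
  structure(list(nodes = as.integer(nodes) - 1L, start = start,
                 period = period, count = as.integer(count), dur = dur,
                 amp = amp), class = "stim_train")
}

#' Run a monodomain simulation
#'
#' Operator-split integration: Rush-Larsen/forward-Euler reaction step from
#' the compiled kernel, then explicit diffusion through the sparse operator.
#' Fully deterministic for a given configuration; the returned final state
#' can be passed back in to continue a run (checkpoint/restart).
#'
#' @param domain a `tissue_domain`.
#' @param stims list of [stim_train()] objects (or a single one).
#' @param duration simulated time (ms).
#' @param dt reaction/diffusion time step (ms, default 0.02).
#' @param state0 optional state matrix (21 x n) to start from; default is
#'   the quiescent resting state at every node.
#' @param t0 simulation clock at entry (ms).
#' @param map_every sampling interval for full voltage maps (ms; 0 = none).
#' @param map_window numeric `c(from, to)` limiting map sampling (ms).
#' @param probes node indices recorded at full detail (V, Cai, INa, INaCa,
#'   ICaL, IKACh).
#' @param probe_every probe sampling interval (ms, default 0.5).
#' @param operator optional precomputed diffusion operator.
#' @param act_thresh activation-detection threshold (mV).
#' @return A `sim_result` with map samples, probe traces, activation events
#'   (node, time), the stimulus log and the final state.
#' @export
run_tissue <- function(domain, stims = list(), duration, dt = 0.02,
                       state0 = NULL, t0 = 0, map_every = 0,
                       map_window = c(0, Inf), probes = integer(0),
                       probe_every = 0.5, operator = NULL,
                       act_thresh = -40) {
  if (inherits(stims, "stim_train")) stims <- list(stims)
  if (duration / dt > 5e7) stop("step budget exceeded: duration/dt = ",
                                duration / dt)
  if (is.null(operator)) operator <- build_diffusion_operator(domain)
  csr <- .csr_parts(operator)
  if (is.null(state0)) {
    state0 <- matrix(crn_initial_state(), nrow = 21, ncol = domain$n)
  }
  stopifnot(nrow(state0) == 21, ncol(state0) == domain$n)
  if (isTRUE(getOption("atriagp.verbose")))
    message(sprintf("[run_tissue] %d nodes, %.0f ms from t0=%.0f (dt=%g)",
                    domain$n, duration, t0, dt))
  vp <- t(vapply(domain$variants, function(v)
    c(v$gCaL_scale, v$gNCX_scale, v$gK1_scale, v$gto_scale, v$gKur_scale,
      v$gKr_scale, v$gKs_scale, v$INa_inact_shift, v$ACh, v$rel_scale,
      v$leak_scale), numeric(11)))
  vp <- matrix(vp, ncol = 11)
  map_to <- if (is.finite(map_window[2])) map_window[2] else t0 + duration
  out <- sim_run_cpp(state0, domain$vidx - 1L, vp, domain$ach,
                     domain$lesion, csr$p, csr$j, csr$x,
                     dt, duration, t0, lapply(stims, unclass),
                     map_every, map_window[1], map_to,
                     as.integer(probes) - 1L, probe_every, act_thresh)
  res <- list(domain = domain, dt = dt, t0 = t0, duration = duration,
              map_times = out$map_times, Vmap = out$Vmap,
              probe_nodes = as.integer(probes),
              probe_times = out$probe_times, probes = out$probes,
              activations = data.frame(node = out$act_node,
                                       time = out$act_time),
              stim_log = data.frame(time = out$stim_times,
                                    train = out$stim_train + 1L),
              final_state = out$final_state)
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$duration, " ms from t0 = ", x$t0, " ms on ",
      x$domain$n, " nodes\n", sep = "")
  cat("  maps: ", length(x$map_times), " frames; probes: ",
      length(x$probe_nodes), "; activations: ", nrow(x$activations), "\n",
      sep = "")
  invisible(x)
}

#' Extract a probe trace
#'
#' @param result a `sim_result`.
#' @param which probe position (index into `probes` passed to [run_tissue()]).
#' @return Data frame with time, V, Cai, INa, INaCa, ICaL, IKACh.
#' @export
probe_trace <- function(result, which = 1) {
  p <- result$probes[[which]]
  data.frame(time = result$probe_times, V = p$V, Cai = p$Cai, INa = p$INa,
             INaCa = p$INaCa, ICaL = p$ICaL, IKACh = p$IKACh)
}

#' Number of activations per node in a time window
#'
#' @param result a `sim_result`.
#' @param window numeric `c(from, to)` in ms (default: whole run).
#' @return Integer vector of length n.
#' @export
activation_counts <- function(result, window = c(-Inf, Inf)) {
  a <- result$activations
  a <- a[a$time >= window[1] & a$time <= window[2], ]
  counts <- integer(result$domain$n)
  if (nrow(a)) {
    tb <- table(a$node)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  counts
}

#' Single-cell simulation through the tissue kernel
#'
#' Convenience wrapper: a 1-node domain with zero diffusion, identical
#' numerics to the tissue integration.
#'
#' @param variant a [model_variant()].
#' @param stim_times vector of stimulus onset times (ms).
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param state0 optional initial state vector.
#' @param stim_amp,stim_dur pulse amplitude (pA/pF) and width (ms).
#' @param probe_every probe sampling interval (ms).
#' @return A `sim_result` with one probe at the cell.
#' @export
simulate_cell <- function(variant = model_variant(), stim_times = numeric(),
                          duration, dt = 0.02, state0 = NULL,
                          stim_amp = -40, stim_dur = 2, probe_every = 0.5) {
  dom <- tissue_grid(1, 1, dx = 250, D = 0)
  dom <- set_variants(dom, variant)
  stims <- lapply(stim_times, function(t0)
    stim_train(1, start = t0, period = 1e9, count = 1, dur = stim_dur,
               amp = stim_amp))
  if (!is.null(state0)) state0 <- matrix(state0, ncol = 1)
  run_tissue(dom, stims, duration, dt = dt, state0 = state0, probes = 1,
             probe_every = probe_every,
             operator = Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                             dims = c(1, 1)))
}

#' Measure planar conduction velocity
#'
#' Paces the left edge of a sheet (or first node of a cable) and measures CV
#' from activation times at 1/4 and 3/4 of the domain length.
#'
#' @param domain a grid `tissue_domain`.
#' @param dt time step (ms).
#' @param amp stimulus amplitude (pA/pF); the default is strong enough to
#'   launch a wave into the edge-column sink across the physiological D
#'   range.
#' @return CV in m/s (= mm/ms).
#' @export
measure_planar_cv <- function(domain, dt = 0.02, amp = -80) {
  stopifnot(domain$type == "grid")
  nx <- domain$nx; ny <- domain$ny
  # stimulate a 0.5-mm-deep strip so the launch succeeds at any resolution
  ncols <- max(1L, round(0.5 / domain$dx))
  left <- which(rep(seq_len(nx), ny) <= ncols)
  res <- run_tissue(domain, stim_train(left, start = 5, period = 1e9,
                                       count = 1, amp = amp),
                    duration = 30 + nx * domain$dx / 0.15, dt = dt)
  midrow <- (ny %/% 2) * nx  # row offset
  n1 <- midrow + max(1L, round(nx * 0.25))
  n2 <- midrow + round(nx * 0.75)
  a <- res$activations
  t1 <- a$time[a$node == n1][1]
  t2 <- a$time[a$node == n2][1]
  if (is.na(t1) || is.na(t2)) stop("wave did not capture both measurement nodes")
  (domain$coords[n2, 1] - domain$coords[n1, 1]) / (t2 - t1)
}

#' Find the diastolic stimulus threshold by bisection
#'
#' @param variant a [model_variant()].
#' @param dur pulse width (ms).
#' @param lo,hi bracketing amplitudes (pA/pF, negative).
#' @param tol bisection tolerance (pA/pF).
#' @return Threshold amplitude (pA/pF, negative).
#' @export
find_stim_threshold <- function(variant = model_variant(), dur = 2,
                                lo = -2, hi = -80, tol = 0.5) {
  # bisection on amplitude: capture = peak V above 0 mV after the pulse
  test <- function(amp) {
    r <- simulate_cell(variant, stim_times = 10, duration = 80,
                       stim_amp = amp, stim_dur = dur)
    max(probe_trace(r)$V) > 0
  }
  if (!test(hi)) stop("upper bracket does not capture")
  if (test(lo)) return(lo)
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (test(mid)) hi <- mid else lo <- mid
  }
  hi
}
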