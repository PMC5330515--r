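# Deterministic ground-truth fixtures for the analysis operations: phase
# movies with known singularities, electrogram trains with known deflection
# times, and analytic action potentials with known APD/EAD truth.

#' Generate a ground-truth fixture
#'
#' Every fixture returns both the data and its exact ground truth, and is
#' fully deterministic given `seed`.
#'
#' Kinds:
#' \describe{
#'   \item{`analytic_spiral`}{Phase movie `phi = atan2(y-y0, x-x0) - w*t`
#'     on an nx x ny grid: exactly one singularity of chirality +1 at the
#'     center.}
#'   \item{`spiral_pair`}{`phi = arg((z-c1)/(z-c2)) - w*t`: two
#'     singularities of opposite chirality (figure-of-eight), net charge 0.}
#'   \item{`chaotic_multirotor`}{Sum of `n` rotating spiral phase fields
#'     with drifting centers; truth lists each seeded core's per-frame
#'     position and chirality.}
#'   \item{`planar_wave_movie`}{Voltage movie of a periodic planar pulse
#'     train crossing the grid; truth holds the passage times per node.}
#'   \item{`deflection_train`}{Electrogram with biphasic deflections at
#'     periodic (or Poisson) times; truth holds the deflection times and the
#'     implied CFAE-CL.}
#'   \item{`trapezoid_ap`}{Piecewise-linear action potential (rest -80 mV,
#'     instantaneous upstroke to +20, plateau, linear repolarization);
#'     optional injected secondary hump for EAD-detector truth.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param ... kind-specific parameters, see Details in the source.
#' @param seed integer seed.
#' @return List with `data` (kind-specific) and `truth`.
#' @export
make_fixture <- function(kind = c("analytic_spiral", "spiral_pair",
                                  "planar_wave_movie", "deflection_train",
                                  "chaotic_multirotor", "trapezoid_ap"),
                         ..., seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
         analytic_spiral = fixture_spiral(..., seed = seed),
         spiral_pair = fixture_spiral_pair(..., seed = seed),
         chaotic_multirotor = fixture_multirotor(..., seed = seed),
         planar_wave_movie = fixture_planar(..., seed = seed),
         deflection_train = fixture_train(..., seed = seed),
         trapezoid_ap = fixture_trapezoid(..., seed = seed))
}

fixture_spiral <- function(nx = 30, ny = 30, center = c(15.2, 15.3),
                           omega = 2 * pi / 100, n_frames = 20, dt = 1,
                           chirality = 1, seed = 1) {
  xs <- seq_len(nx); ys <- seq_len(ny)
  frames <- array(0, c(nx, ny, n_frames))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    frames[, , f] <- outer(xs, ys, function(x, y)
      wrap_pi(chirality * atan2(y - center[2], x - center[1]) - omega * t))
  }
  list(data = list(phase = frames, times = (seq_len(n_frames) - 1) * dt),
       truth = list(n_ps = 1, centers = matrix(center, 1),
                    chirality = chirality))
}

fixture_spiral_pair <- function(nx = 40, ny = 30, c1 = c(12.3, 15.2),
                                c2 = c(27.6, 15.4), omega = 2 * pi / 100,
                                n_frames = 20, dt = 1, seed = 1) {
  xs <- seq_len(nx); ys <- seq_len(ny)
  frames <- array(0, c(nx, ny, n_frames))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    frames[, , f] <- outer(xs, ys, function(x, y)
      wrap_pi(atan2(y - c1[2], x - c1[1]) - atan2(y - c2[2], x - c2[1]) -
                omega * t))
  }
  list(data = list(phase = frames, times = (seq_len(n_frames) - 1) * dt),
       truth = list(n_ps = 2, centers = rbind(c1, c2),
                    chirality = c(1, -1)))
}

fixture_multirotor <- function(nx = 40, ny = 40, n = 4, omega = 2 * pi / 120,
                               drift = 0.05, n_frames = 30, dt = 1,
                               seed = 1) {
  set.seed(seed)
  # rejection-sample well-separated cores so opposite charges cannot cancel
  # within one plaquette and every seeded core is individually detectable
  min_sep <- min(nx, ny) * 0.2
  repeat {
    centers0 <- cbind(runif(n, nx * 0.2, nx * 0.8),
                      runif(n, ny * 0.2, ny * 0.8))
    if (n < 2 || min(stats::dist(centers0)) >= min_sep) break
  }
  chir <- rep(c(1, -1), length.out = n)
  vel <- matrix(rnorm(2 * n, 0, drift), n, 2)
  xs <- seq_len(nx); ys <- seq_len(ny)
  frames <- array(0, c(nx, ny, n_frames))
  centers <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    cf <- centers0 + vel * t
    centers[[f]] <- cf
    ph <- outer(xs, ys, function(x, y) {
      s <- 0
      for (k in seq_len(n))
        s <- s + chir[k] * atan2(y - cf[k, 2], x - cf[k, 1])
      s - omega * t
    })
    frames[, , f] <- wrap_pi(ph)
  }
  list(data = list(phase = frames, times = (seq_len(n_frames) - 1) * dt),
       truth = list(n_ps = n, centers_by_frame = centers, chirality = chir))
}

fixture_planar <- function(nx = 50, ny = 5, dx = 0.25, cv = 0.5,
                           period = 150, n_cycles = 4, apd = 80, dt = 1,
                           repol = 30, v_rest = -80, v_peak = 20, seed = 1) {
  duration <- n_cycles * period + nx * dx / cv + apd + repol
  times <- seq(0, duration, by = dt)
  n <- nx * ny
  maps <- matrix(v_rest, n, length(times))
  xcoord <- rep((seq_len(nx) - 1) * dx, ny)
  passage <- matrix(NA_real_, n, n_cycles)
  for (c_ in seq_len(n_cycles)) {
    t_arr <- (c_ - 1) * period + xcoord / cv
    passage[, c_] <- t_arr
    for (i in seq_len(n)) {
      on <- times >= t_arr[i] & times < t_arr[i] + apd
      maps[i, on] <- v_peak
      # gradual repolarization so only the upstroke registers as a deflection
      ramp <- which(times >= t_arr[i] + apd & times < t_arr[i] + apd + repol)
      maps[i, ramp] <- v_peak - (v_peak - v_rest) *
        (times[ramp] - t_arr[i] - apd) / repol
    }
  }
  coords <- cbind(x = xcoord, y = rep((seq_len(ny) - 1) * dx, each = nx))
  list(data = list(maps = maps, times = times, coords = coords,
                   nx = nx, ny = ny),
       truth = list(passage_times = passage, period = period, cv = cv))
}

fixture_train <- function(duration = 6000, interval = 150,
                          mode = c("periodic", "poisson"), rate = NULL,
                          dt = 1, amp = 1, width = 6, noise_sd = 0,
                          min_sep = 45, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "periodic") {
    defl <- seq(width + 10, duration - width - 10, by = interval)
  } else {
    if (is.null(rate)) rate <- 1 / interval
    defl <- numeric(0); t <- width + 10
    repeat {
      t <- t + rexp(1, rate)
      if (t > duration - width - 10) break
      # minimal separation keeps deflections resolvable under the default
      # detector refractory; the ground truth records the realized times
      if (!length(defl) || t - tail(defl, 1) >= min_sep) defl <- c(defl, t)
    }
  }
  times <- seq(0, duration, by = dt)
  sig <- numeric(length(times))
  for (d in defl) {
    # biphasic wavelet
    sel <- which(abs(times - d) <= width)
    sig[sel] <- sig[sel] + amp * (times[sel] - d) / width *
      exp(-((times[sel] - d) / (width / 2))^2)
  }
  if (noise_sd > 0) sig <- sig + rnorm(length(sig), 0, noise_sd)
  list(data = data.frame(time = times, signal = sig),
       truth = list(deflection_times = defl,
                    cl = if (length(defl) >= 2) mean(diff(defl)) else NA_real_))
}

fixture_trapezoid <- function(rest = -80, peak = 20, plateau = 200,
                              repol = 100, t_up = 50, duration = 500,
                              dt = 0.5, ead_amp = 0, ead_at = -50,
                              seed = 1) {
  times <- seq(0, duration, by = dt)
  V <- rep(rest, length(times))
  amp <- peak - rest
  for (i in seq_along(times)) {
    t <- times[i]
    if (t >= t_up && t < t_up + 1) V[i] <- rest + amp * (t - t_up)  # 1-ms rise
    else if (t >= t_up + 1 && t < t_up + plateau) V[i] <- peak
    else if (t >= t_up + plateau && t < t_up + plateau + repol)
      V[i] <- peak - (peak - rest) * (t - t_up - plateau) / repol
  }
  truth_apd90 <- plateau + 0.9 * repol
  t_take <- NA_real_
  if (ead_amp > 0) {
    # inject a hump starting where V crosses ead_at on the downslope
    t_take <- t_up + plateau + (peak - ead_at) / (peak - rest) * repol
    sel <- which(times >= t_take & times < t_take + 40)
    V[sel] <- pmax(V[sel], ead_at + ead_amp * sin(pi * (times[sel] - t_take) / 40))
  }
  list(data = data.frame(time = times, V = V),
       truth = list(apd90 = truth_apd90, apd50 = plateau + 0.5 * repol,
                    stim_time = t_up, ead = ead_amp >= 10,
                    ead_takeoff = if (ead_amp > 0) ead_at else NA_real_,
                    t_takeoff = t_take))
}
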