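# Virtual bipolar electrograms and complex-fractionated-electrogram cycle
# length (CFAE-CL) mapping.

#' Virtual bipolar electrogram at a node
#'
#' Distance-weighted sum of -dV/dt over nodes within `radius` of the
#' recording node, minus the same sum at an offset pole (common-mode
#' rejection is exact because the weights are normalized). Linear in V.
#'
#' @param maps nodes x time voltage matrix (mV).
#' @param times sample times (ms).
#' @param coords node coordinates (n x 2 or n x 3, mm).
#' @param node recording node index.
#' @param radius summation radius (mm).
#' @param pole_offset distance (mm) to the second pole (the nearest node at
#'   least this far away is used).
#' @param falloff distance scale (mm) of the 1/(1+(d/falloff)^2) weighting.
#' @return Data frame with `time` (midpoints) and `signal`.
#' @export
virtual_electrogram <- function(maps, times, coords, node, radius = 2,
                                pole_offset = 1.5, falloff = 0.5) {
  coords <- as.matrix(coords)
  d1 <- sqrt(rowSums(sweep(coords, 2, coords[node, ])^2))
  far <- which(d1 >= pole_offset)
  pole2 <- far[which.min(d1[far])]
  d2 <- sqrt(rowSums(sweep(coords, 2, coords[pole2, ])^2))
  w <- function(d) {
    wt <- ifelse(d <= radius, 1 / (1 + (d / falloff)^2), 0)
    wt / sum(wt)
  }
  w1 <- w(d1); w2 <- w(d2)
  dvdt <- diff(t(maps)) / diff(times)  # (nt-1) x n
  sig <- as.numeric(dvdt %*% (w2 - w1))  # -dV/dt weighted: w1 - w2 on -dvdt
  data.frame(time = (times[-1] + times[-length(times)]) / 2, signal = sig)
}

#' Deflection times of an electrogram
#'
#' Local maxima of |signal| above an amplitude threshold, separated by at
#' least the refractory interval.
#'
#' @param signal,times electrogram samples; a data frame with `time` and
#'   `signal` may be given as `signal`.
#' @param threshold amplitude threshold; default 20% of the maximal
#'   |signal|.
#' @param refractory minimal deflection separation (ms, default 40).
#' @return Numeric vector of deflection times (ms).
#' @export
detect_deflections <- function(signal, times = NULL, threshold = NULL,
                               refractory = 40) {
  if (is.data.frame(signal)) { times <- signal$time; signal <- signal$signal }
  a <- abs(signal)
  if (is.null(threshold)) threshold <- 0.2 * max(a)
  n <- length(a)
  if (n < 3) return(numeric(0))
  ispeak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] &
                a[2:(n - 1)] > a[3:n], FALSE) & a >= threshold
  cand <- which(ispeak)
  out <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (times[i] - last >= refractory) { out <- c(out, times[i]); last <- times[i] }
  }
  out
}

#' CFAE cycle length of one electrogram
#'
#' Mean interval between consecutive deflections over the analysis window.
#'
#' @inheritParams detect_deflections
#' @param window optional `c(from, to)` (ms) restricting the analysis.
#' @return List with `cl` (ms, `NA` if fewer than 2 deflections),
#'   `n_deflections`, and `defined`.
#' @export
cfae_cl <- function(signal, times = NULL, threshold = NULL, refractory = 40,
                    window = NULL) {
  if (is.data.frame(signal)) { times <- signal$time; signal <- signal$signal }
  if (!is.null(window)) {
    sel <- times >= window[1] & times <= window[2]
    times <- times[sel]; signal <- signal[sel]
  }
  defl <- detect_deflections(signal, times, threshold, refractory)
  if (length(defl) < 2)
    return(list(cl = NA_real_, n_deflections = length(defl), defined = FALSE))
  list(cl = mean(diff(defl)), n_deflections = length(defl), defined = TRUE)
}

#' CFAE-CL map over all nodes
#'
#' Computes a virtual electrogram and its CFAE-CL at every node (or a
#' subset) and the CFAE-area mask (CFAE-CL at or below the threshold;
#' 120 ms by convention).
#'
#' @param maps,times,coords as in [virtual_electrogram()].
#' @param nodes node indices to map (default: all).
#' @param cfae_threshold CFAE-area threshold (ms).
#' @param ... passed to [virtual_electrogram()] and [cfae_cl()].
#' @return A `cfae_map`: data frame with `node`, `cl`, `n_deflections`, and
#'   logical `cfae_area`.
#' @export
cfae_map <- function(maps, times, coords, nodes = NULL, cfae_threshold = 120,
                     radius = 2, pole_offset = 1.5, threshold = NULL,
                     refractory = 40) {
  if (is.null(nodes)) nodes <- seq_len(nrow(maps))
  res <- lapply(nodes, function(i) {
    eg <- virtual_electrogram(maps, times, coords, i, radius, pole_offset)
    cc <- cfae_cl(eg, threshold = threshold, refractory = refractory)
    data.frame(node = i, cl = cc$cl, n_deflections = cc$n_deflections)
  })
  out <- do.call(rbind, res)
  out$cfae_area <- !is.na(out$cl) & out$cl <= cfae_threshold
  class(out) <- c("cfae_map", class(out))
  out
}
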