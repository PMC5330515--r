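# Per-beat action potential feature extraction and early-afterdepolarization
# detection on sampled voltage traces.

#' Extract per-beat action potential features
#'
#' Splits a voltage trace into beat windows at the stimulus times and
#' measures, for each captured beat: maximal upstroke velocity, peak
#' potential, diastolic (pre-stimulus) potential, APD50/APD90 (from the time
#' of maximal dV/dt to 50%/90% repolarization of that beat's amplitude), and
#' the EAD flag from [detect_ead()].
#'
#' @param time,V trace sample times (ms, at most 1 ms apart) and potentials
#'   (mV). A data frame with `time` and `V` columns may be given as `time`.
#' @param stim_times stimulus onset times (ms); beats are windows between
#'   consecutive stimuli.
#' @param capture_dvdt minimal dV/dt (mV/ms) of the upstroke; together with
#'   a peak of at least `capture_peak` it defines a captured beat (the peak
#'   requirement rejects sub-threshold stimulus artifacts).
#' @param capture_peak minimal peak potential (mV) of a captured beat.
#' @param stim_dur stimulus pulse width (ms), retained in the window for the
#'   upstroke search (direct pacing merges artifact and upstroke).
#' @return Data frame with one row per stimulus: `beat`, `t_stim`,
#'   `captured`, `t_upstroke`, `dvdt_max`, `v_peak`, `v_diastolic`, `apd50`,
#'   `apd90`, `ead`, `ead_takeoff`.
#' @export
extract_ap_features <- function(time, V = NULL, stim_times,
                                capture_dvdt = 10, capture_peak = -20,
                                stim_dur = 2) {
  if (is.data.frame(time)) { V <- time$V; time <- time$time }
  stopifnot(length(time) == length(V), length(stim_times) >= 1)
  if (max(diff(time)) > 1 + 1e-9)
    stop("trace must be sampled at 1 ms or finer")
  stim_times <- sort(stim_times)
  n <- length(stim_times)
  ends <- c(stim_times[-1], max(time))
  out <- vector("list", n)
  for (b in seq_len(n)) {
    t0 <- stim_times[b]; t1 <- ends[b]
    pre <- which(time < t0)
    v_dia <- if (length(pre)) V[max(pre)] else V[1]
    sel <- which(time >= t0 & time <= t1)
    row <- data.frame(beat = b, t_stim = t0, captured = FALSE,
                      t_upstroke = NA_real_, dvdt_max = NA_real_,
                      v_peak = NA_real_, v_diastolic = v_dia,
                      apd50 = NA_real_, apd90 = NA_real_, ead = FALSE,
                      ead_takeoff = NA_real_)
    if (length(sel) > 3) {
      tt <- time[sel]; vv <- V[sel]
      dv <- diff(vv) / diff(tt)
      iu <- which.max(dv)
      if (dv[iu] >= capture_dvdt && max(vv) >= capture_peak) {
        row$captured <- TRUE
        row$t_upstroke <- tt[iu]
        row$dvdt_max <- dv[iu]
        pk <- which.max(vv)
        row$v_peak <- vv[pk]
        amp <- row$v_peak - v_dia
        rep_level <- function(frac) {
          vtarget <- row$v_peak - frac * amp
          after <- which(tt > tt[pk] & vv <= vtarget)
          if (length(after)) tt[after[1]] - row$t_upstroke else NA_real_
        }
        row$apd50 <- rep_level(0.5)
        row$apd90 <- rep_level(0.9)
        ed <- detect_ead(tt, vv)
        row$ead <- ed$ead
        row$ead_takeoff <- ed$takeoff
      }
    }
    out[[b]] <- row
  }
  do.call(rbind, out)
}

#' Detect an early afterdepolarization within one beat
#'
#' Operational rule: after the beat's peak, while the membrane repolarizes,
#' an EAD is called if the potential reaches a local minimum inside the
#' take-off window (default -60 to -20 mV) and subsequently rises by at
#' least `min_rise` mV above the running minimum before the window ends.
#'
#' @param time,V samples of one beat (peak included). A data frame with
#'   `time` and `V` may be given as `time`.
#' @param window take-off voltage window (mV).
#' @param min_rise required depolarizing excursion above the running local
#'   minimum (mV).
#' @return List with `ead` (logical), `takeoff` (mV, potential at the local
#'   minimum, or `NA`), `t_takeoff` (ms).
#' @export
detect_ead <- function(time, V = NULL, window = c(-60, -20), min_rise = 10) {
  if (is.data.frame(time)) { V <- time$V; time <- time$time }
  pk <- which.max(V)
  res <- list(ead = FALSE, takeoff = NA_real_, t_takeoff = NA_real_)
  if (pk >= length(V) - 2) return(res)
  vv <- V[pk:length(V)]; tt <- time[pk:length(V)]
  rmin <- cummin(vv)
  rise <- vv - rmin
  hit <- which(rise >= min_rise & rmin >= window[1] & rmin <= window[2])
  if (length(hit)) {
    i <- hit[1]
    j <- which(vv[1:i] == rmin[i])[1]
    res$ead <- TRUE
    res$takeoff <- rmin[i]
    res$t_takeoff <- tt[j]
  }
  res
}
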