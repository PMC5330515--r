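# Pacing and induction protocols, virtual ablation patterns, and
# post-ablation outcome classification.

#' Run the 2D EAD pacing protocol
#'
#' 20 x 20 sheet (250-um spacing) of PV-variant cells under the combined
#' autonomic condition; one edge is paced `n_fast` times at `first_pcl`,
#' then the cycle length switches to `second_pcl`. Returns per-beat features
#' at a central probe, the diastolic potential immediately before the last
#' fast stimulus, and EAD flags for the post-change beats.
#'
#' The "first post-change beat" is the first beat delivered at the new cycle
#' length (its diastolic interval is the first long one); an EAD detected
#' during the pause that follows the final fast beat is also attributed to
#' the cycle-length change.
#'
#' @param first_pcl,second_pcl pacing cycle lengths (ms).
#' @param n_fast number of fast-phase stimuli (default 200).
#' @param n_slow number of slow-phase stimuli simulated (>= 2 so that
#'   "first beat only" can be verified).
#' @param ACh acetylcholine concentration (uM).
#' @param ical_fold,ncx_fold,ina_shift autonomic modifications (see
#'   [apply_ans_stimulation()]).
#' @param nx,ny,dx sheet dimensions (nodes) and spacing (um).
#' @param D diffusion coefficient (mm^2/ms).
#' @param dt time step (ms).
#' @param stim_amp edge-stimulus amplitude (pA/pF); the default is twice the
#'   measured edge-pacing diastolic threshold.
#' @param base_variant starting variant before the PV conversion and
#'   autonomic modifications (default control LA).
#' @param pv logical: apply the PV scaling table (default `TRUE`).
#' @return List of class `ead2d_result`: `features` (per-beat data frame),
#'   `diastolic_end_pacing` (mV), `ead_first_beat`, `ead_later_beats`,
#'   `trace` (probe data frame) and `sim` (the `sim_result`).
#' @export
run_2d_ead_protocol <- function(first_pcl = 100, second_pcl = 1000,
                                n_fast = 200, n_slow = 3, ACh = 0.05,
                                ical_fold = 7, ncx_fold = 2, ina_shift = 10,
                                nx = 20, ny = 20, dx = 250,
                                D = default_diffusion(), dt = 0.02,
                                stim_amp = -72,
                                base_variant = model_variant(), pv = TRUE) {
  v <- base_variant
  if (pv) v <- apply_pv_variant(v)
  v <- apply_ans_stimulation(v, ACh = ACh, ical_fold = ical_fold,
                             ncx_fold = ncx_fold, ina_shift_mV = ina_shift)
  dom <- set_variants(tissue_grid(nx, ny, dx, D = D), v)
  left <- which(rep(seq_len(nx), ny) == 1)
  t_change <- (n_fast - 1) * first_pcl
  fast <- stim_train(left, start = 0, period = first_pcl, count = n_fast,
                     amp = stim_amp)
  slow <- stim_train(left, start = t_change + second_pcl,
                     period = second_pcl, count = n_slow, amp = stim_amp)
  duration <- t_change + (n_slow + 0.9) * second_pcl
  probe <- (ny %/% 2 - 1) * nx + nx %/% 2  # central node
  sim <- run_tissue(dom, list(fast, slow), duration, dt = dt,
                    probes = probe, probe_every = 0.5)
  tr <- probe_trace(sim)
  stims <- c((0:(n_fast - 1)) * first_pcl,
             t_change + second_pcl * seq_len(n_slow))
  feats <- extract_ap_features(tr$time, tr$V, stims)
  dia <- tr$V[max(which(tr$time < t_change))]
  post <- feats[feats$beat >= n_fast, , drop = FALSE]
  ead_first <- any(post$ead[post$beat %in% c(n_fast, n_fast + 1)])
  ead_later <- any(post$ead[post$beat > n_fast + 1])
  structure(list(features = feats, diastolic_end_pacing = dia,
                 ead_first_beat = ead_first, ead_later_beats = ead_later,
                 trace = tr, sim = sim,
                 params = list(first_pcl = first_pcl,
                               second_pcl = second_pcl, n_fast = n_fast,
                               ACh = ACh, ical_fold = ical_fold,
                               ncx_fold = ncx_fold, ina_shift = ina_shift)),
            class = "ead2d_result")
}

#' @export
print.ead2d_result <- function(x, ...) {
  cat("<ead2d_result> PCL ", x$params$first_pcl, " -> ",
      x$params$second_pcl, " ms\n", sep = "")
  cat("  diastolic at end of fast pacing: ",
      round(x$diastolic_end_pacing, 2), " mV\n", sep = "")
  cat("  EAD on first post-change beat: ", x$ead_first_beat,
      "; on later beats: ", x$ead_later_beats, "\n", sep = "")
  invisible(x)
}

#' Scan a parameter of the 2D EAD protocol for the EAD onset
#'
#' Runs the protocol at increasing parameter values and reports the smallest
#' value for which the EAD appears on the first post-change beat.
#'
#' @param param one of `"ncx_fold"`, `"ical_fold"`, `"first_pcl"`,
#'   `"second_pcl"`.
#' @param values increasing values to scan.
#' @param early_stop stop at the first EAD-positive value (the scan is for
#'   the smallest positive value, so points above it are uninformative).
#' @param ... fixed arguments to [run_2d_ead_protocol()].
#' @return List with `onset` (smallest positive value, `NA` if none) and
#'   `results` (named logical vector of EAD flags per scanned value).
#' @export
scan_ead_onset <- function(param, values, early_stop = TRUE, ...) {
  flags <- setNames(rep(NA, length(values)), values)
  onset <- NA_real_
  for (i in seq_along(values)) {
    args <- list(...)
    args[[param]] <- values[i]
    res <- do.call(run_2d_ead_protocol, args)
    flags[i] <- res$ead_first_beat
    if (flags[i]) { onset <- values[i]; if (early_stop) break }
  }
  list(onset = onset, flags = flags)
}

# pacing-site helpers ------------------------------------------------------

#' Pacing site vertex sets on the LA geometry
#'
#' `lspv_pacing_site`: a small patch inside the left superior PV sleeve near
#' the ostium; `bachmann_pacing_site`: the BachmannSite region.
#'
#' @param geom an `la_geometry`.
#' @param radius patch radius (mm).
#' @return Integer vertex indices.
#' @export
lspv_pacing_site <- function(geom, radius = 2) {
  pv1 <- which(geom$region == "PV1")
  d <- geodesic_distance(geom, geom$loops$PV1)
  seed_v <- pv1[which.min(d[pv1])]
  which(geodesic_distance(geom, seed_v) <= radius)
}

#' @rdname lspv_pacing_site
#' @export
bachmann_pacing_site <- function(geom) {
  which(geom$region == "BachmannSite")
}

#' Run the 3D pulmonary-vein trigger protocol
#'
#' Dual-site pacing on the LA surface: the left superior PV is paced at
#' `fast_pcl` from 0 to `fast_until`, and the Bachmann-bundle site at
#' `slow_pcl` from 0 to `slow_until` (simulated sinus rhythm). The autonomic
#' condition (ICaL fold, NCX fold, INa shift) is applied homogeneously; ACh
#' acts through the GP layout's spatial field.
#'
#' @param geom an [generate_idealized_la()] geometry.
#' @param layout a [generate_gp_octopus()] layout (or `NULL` for no ACh).
#' @param ical_fold,ncx_fold,ina_shift autonomic modifications.
#' @param fast_pcl,fast_until fast PV pacing cycle length and end time (ms).
#' @param slow_pcl,slow_until background pacing cycle length and end time.
#' @param duration total simulated time (ms).
#' @param D diffusion coefficient; `dt` time step (ms).
#' @param stim_amp stimulus amplitude (pA/pF).
#' @param map_every optional voltage-map sampling interval (ms).
#' @return List of class `trigger3d_result`: the `sim_result`, probe layout,
#'   and the spontaneous-activation summary from
#'   [spontaneous_pv_activations()].
#' @export
run_3d_trigger_protocol <- function(geom, layout = NULL, ical_fold = 7,
                                    ncx_fold = 2, ina_shift = 10,
                                    fast_pcl = 100, fast_until = 7000,
                                    slow_pcl = 1000, slow_until = 20000,
                                    duration = 12000,
                                    D = default_diffusion(), dt = 0.02,
                                    stim_amp = -72, map_every = 0) {
  ans <- function(v) apply_ans_stimulation(v, ACh = 0, ical_fold = ical_fold,
                                           ncx_fold = ncx_fold,
                                           ina_shift_mV = ina_shift)
  dom <- la_tissue_domain(geom, layout,
                          la_variant = ans(model_variant()),
                          pv_variant = ans(apply_pv_variant(model_variant())),
                          D = D)
  site_pv <- lspv_pacing_site(geom)
  site_bb <- bachmann_pacing_site(geom)
  fast <- stim_train(site_pv, start = 0, period = fast_pcl,
                     count = max(1, floor(fast_until / fast_pcl)),
                     amp = stim_amp)
  slow <- stim_train(site_bb, start = 0, period = slow_pcl,
                     count = max(1, floor(min(slow_until, duration) / slow_pcl)),
                     amp = stim_amp)
  # probes: pacing site, PV adjacent, antrum, mid LA, far LA
  d_site <- geodesic_distance(geom, site_pv[1])
  pick <- function(region, lo, hi) {
    cand <- which(as.character(geom$region) %in% region &
                    d_site >= lo & d_site <= hi)
    if (!length(cand)) cand <- which.min(abs(d_site - (lo + hi) / 2))
    cand[which.min(abs(d_site[cand] - (lo + hi) / 2))]
  }
  probes <- c(site_pv[1],
              pick("PV1", 2, 5),
              pick("LA", 6, 11),
              pick("LA", 15, 22),
              pick("LA", 28, 40))
  sim <- run_tissue(dom, list(fast, slow), duration, dt = dt,
                    probes = probes, probe_every = 1,
                    map_every = map_every)
  spont <- spontaneous_pv_activations(sim, geom, t_from = fast_until + 50,
                                      t_to = duration)
  structure(list(sim = sim, probes = probes, spontaneous = spont,
                 geom = geom, layout = layout,
                 params = list(ical_fold = ical_fold, ncx_fold = ncx_fold,
                               ina_shift = ina_shift, fast_pcl = fast_pcl,
                               fast_until = fast_until,
                               duration = duration)),
            class = "trigger3d_result")
}

#' Count spontaneous (non-paced) PV activations
#'
#' An activation of a PV-region vertex in the analysis window counts as
#' spontaneous if no stimulus was delivered (at any site) within the
#' preceding `exclusion` ms — conducted beats from the background pacing are
#' thereby excluded.
#'
#' @param sim a `sim_result`.
#' @param geom the `la_geometry` used to build the domain.
#' @param t_from,t_to analysis window (ms).
#' @param exclusion stimulus-attribution window (ms).
#' @return List with `count`, `nodes` (distinct PV vertices involved) and
#'   `times`.
#' @export
spontaneous_pv_activations <- function(sim, geom, t_from, t_to,
                                       exclusion = 300) {
  pv <- which(grepl("^PV", as.character(geom$region)))
  a <- sim$activations
  a <- a[a$node %in% pv & a$time >= t_from & a$time <= t_to, , drop = FALSE]
  if (!nrow(a)) return(list(count = 0L, nodes = integer(0), times = numeric(0)))
  stim_t <- sim$stim_log$time
  spont <- vapply(a$time, function(t)
    !any(stim_t <= t & stim_t > t - exclusion), logical(1))
  list(count = sum(spont), nodes = unique(a$node[spont]),
       times = a$time[spont])
}

#' Induce atrial fibrillation by burst pacing
#'
#' Rapid burst pacing at the Bachmann-bundle site of an AF-remodeled LA,
#' followed by a free-running observation window sampled at 1 ms for phase
#' analysis. Non-induction is reported as a result, not an error.
#'
#' @param geom,layout geometry and (optional) GP/ACh layout.
#' @param remodeled logical: apply [apply_af_remodeling()] (default `TRUE`).
#' @param burst_pcls burst stages (ms); each stage delivers `burst_count`
#'   pulses.
#' @param burst_count pulses per stage.
#' @param observe free-running window after the burst (ms).
#' @param map_every map sampling interval during observation (ms).
#' @param D,dt,stim_amp numerics.
#' @param seed jitters the burst cycle lengths by up to +-5 ms.
#' @return List of class `af_result`: `sim` (observation window with maps),
#'   `induced` (activity present in the final 500 ms), `burst_sim`.
#' @export
induce_af <- function(geom, layout = NULL, remodeled = TRUE,
                      burst_pcls = c(130, 110, 95), burst_count = 25,
                      observe = 6000, map_every = 1,
                      D = default_diffusion(), dt = 0.02, stim_amp = -72,
                      seed = 1) {
  set.seed(seed)
  jit <- round(runif(length(burst_pcls), -5, 5))
  pcls <- pmax(60, burst_pcls + jit)
  base <- model_variant()
  if (remodeled) base <- apply_af_remodeling(base)
  dom <- la_tissue_domain(geom, layout, la_variant = base,
                          pv_variant = apply_pv_variant(base), D = D)
  site <- bachmann_pacing_site(geom)
  t0 <- 0
  trains <- list()
  for (s in seq_along(pcls)) {
    trains[[s]] <- stim_train(site, start = t0, period = pcls[s],
                              count = burst_count, amp = stim_amp)
    t0 <- t0 + pcls[s] * burst_count
  }
  burst_dur <- t0 + 200
  burst <- run_tissue(dom, trains, burst_dur, dt = dt)
  obs <- run_tissue(dom, list(), observe, dt = dt,
                    state0 = burst$final_state, t0 = burst_dur,
                    map_every = map_every,
                    map_window = c(burst_dur, burst_dur + observe))
  last_act <- if (nrow(obs$activations)) max(obs$activations$time) else -Inf
  induced <- is.finite(last_act) && last_act >= burst_dur + observe - 500
  structure(list(sim = obs, burst_sim = burst, induced = induced,
                 burst_end = burst_dur, domain = dom, seed = seed),
            class = "af_result")
}

# ablation ------------------------------------------------------------------

#' Construct a virtual ablation pattern
#'
#' Three lesion sets: `GP_ONLY` (the four GP patches), `CPVI_WITH_GP`
#' (closed encircling bands around each PV ostium placed at the antrum,
#' united with the GP patches) and `CPVI_WITHOUT_GP` (closed bands proximal
#' to the ostia, not touching the GP patches). Band closure is verified by a
#' connectivity test ([verify_isolation()]).
#'
#' @param geom an `la_geometry`.
#' @param layout a [generate_gp_octopus()] layout.
#' @param name pattern name.
#' @param band_width lesion band width (mm).
#' @return List of class `ablation_pattern` with `name` and `lesion`
#'   (vertex indices).
#' @export
ablation_pattern <- function(geom, layout,
                             name = c("GP_ONLY", "CPVI_WITH_GP",
                                      "CPVI_WITHOUT_GP"),
                             band_width = 2.5) {
  name <- match.arg(name)
  gp_vts <- unlist(lapply(layout$gps, `[[`, "patch"))
  lesion <- integer(0)
  if (name == "GP_ONLY") {
    lesion <- sort(unique(gp_vts))
  } else {
    sleeve <- geom$params$pv_sleeve
    r0 <- if (name == "CPVI_WITH_GP") sleeve else max(1.5, sleeve - 4.5)
    d_pv <- lapply(1:4, function(k)
      geodesic_distance(geom, geom$loops[[paste0("PV", k)]]))
    # widen the band if the mesh is too coarse for a closed annulus
    for (w in band_width + c(0, 1, 2, 3)) {
      lesion <- integer(0)
      for (k in 1:4) lesion <- c(lesion, which(d_pv[[k]] >= r0 &
                                                 d_pv[[k]] <= r0 + w))
      if (name == "CPVI_WITH_GP") lesion <- c(lesion, gp_vts)
      else lesion <- setdiff(lesion, gp_vts)
      lesion <- sort(unique(lesion))
      if (verify_isolation(geom, lesion)) break
      lesion <- NULL
    }
    if (is.null(lesion))
      stop("CPVI band is not closed: PVs remain connected to the LA body")
  }
  structure(list(name = name, lesion = lesion), class = "ablation_pattern")
}

#' Verify that lesions isolate all PV ostia from the LA body
#'
#' Removes the lesioned vertices from the mesh graph and tests that no path
#' connects any PV ostium rim to the mitral rim.
#'
#' @param geom an `la_geometry`.
#' @param lesion vertex indices.
#' @return Logical.
#' @export
verify_isolation <- function(geom, lesion) {
  keep <- setdiff(seq_len(nrow(geom$vertices)), lesion)
  g2 <- igraph::induced_subgraph(geom$graph, keep)
  comp <- igraph::components(g2)$membership
  idx <- setNames(seq_along(keep), keep)
  mit <- intersect(geom$loops$mitral, keep)
  if (!length(mit)) return(TRUE)
  mit_comp <- unique(comp[idx[as.character(mit)]])
  for (k in 1:4) {
    pvv <- intersect(geom$loops[[paste0("PV", k)]], keep)
    if (!length(pvv)) next
    if (any(comp[idx[as.character(pvv)]] %in% mit_comp)) return(FALSE)
  }
  TRUE
}

#' Apply an ablation pattern to a domain
#'
#' Lesioned nodes are clamped to the resting potential, made non-excitable
#' and removed from the diffusion stencil (no-flux lesion boundaries).
#'
#' @param domain a `tissue_domain`.
#' @param pattern an [ablation_pattern()] (or integer vertex indices).
#' @param state optional state matrix to update in place (lesioned nodes are
#'   reset to rest).
#' @return The domain (and, if `state` was given, a list with `domain` and
#'   `state`).
#' @export
apply_ablation <- function(domain, pattern, state = NULL) {
  lesion <- if (inherits(pattern, "ablation_pattern")) pattern$lesion
  else as.integer(pattern)
  domain <- add_lesion(domain, lesion)
  if (!is.null(state)) {
    state[, lesion] <- crn_initial_state()
    return(list(domain = domain, state = state))
  }
  domain
}

#' Classify the post-ablation rhythm
#'
#' Operational rules (configuration-exposed):
#' \itemize{
#'   \item `Terminated`: no activations in the final `quiet_window` ms of the
#'     observation window; event time = last activation.
#'   \item `AT`: sustained activity whose per-node cycle lengths are regular
#'     (median coefficient of variation below `cv_limit`) and, when phase
#'     maps are available, at most one concurrent long-lived phase
#'     singularity; event time = start of the first analysis window from
#'     which regularity holds.
#'   \item `AF`: otherwise.
#' }
#'
#' @param activations data frame with `node`, `time` (ms), or a
#'   `sim_result`.
#' @param window observation window `c(from, to)` (ms).
#' @param ps_tracks optional result of [track_ps()] over the same window.
#' @param cv_limit cycle-length regularity limit (default 0.10).
#' @param quiet_window termination window (ms, default 2000).
#' @param min_beats minimal activations per node for a CL estimate.
#' @param long_lived_ms PS lifespan defining "long-lived" (ms).
#' @return List of class `af_outcome`: `label` (`"AF"`, `"AT"`,
#'   `"Terminated"`), `event_time` (s from window start; `NA` for AF),
#'   `details`.
#' @export
classify_outcome <- function(activations, window, ps_tracks = NULL,
                             cv_limit = 0.10, quiet_window = 2000,
                             min_beats = 4, long_lived_ms = 500) {
  if (inherits(activations, "sim_result")) activations <- activations$activations
  a <- activations[activations$time >= window[1] &
                     activations$time <= window[2], , drop = FALSE]
  t0 <- window[1]; t1 <- window[2]
  if (!nrow(a) || max(a$time) < t1 - quiet_window) {
    ev <- if (nrow(a)) (max(a$time) - t0) / 1000 else 0
    return(structure(list(label = "Terminated", event_time = ev,
                          details = list(last_activation = if (nrow(a)) max(a$time) else NA)),
                     class = "af_outcome"))
  }
  # per-node cycle-length regularity over sliding 2-s windows
  organized_from <- NA_real_
  win <- 2000
  starts <- seq(t0, t1 - win, by = win / 2)
  org <- vapply(starts, function(s) {
    aa <- a[a$time >= s & a$time < s + win, ]
    cls <- tapply(aa$time, aa$node, function(tt)
      if (length(tt) >= min_beats) stats::sd(diff(tt)) / mean(diff(tt)) else NA_real_)
    cls <- cls[!is.na(cls)]
    length(cls) > 0 && stats::median(cls) < cv_limit
  }, logical(1))
  if (any(org)) {
    # organized from the first window such that every later window is too
    k <- which(rev(cumprod(rev(org))) == 1)
    if (length(k)) organized_from <- starts[k[1]]
  }
  n_conc_ps <- 0
  if (!is.null(ps_tracks)) {
    long_tracks <- Filter(function(tr) (max(tr$time) - min(tr$time)) >= long_lived_ms,
                          ps_tracks$tracks)
    if (length(long_tracks)) {
      times <- sort(unique(unlist(lapply(long_tracks, `[[`, "time"))))
      conc <- vapply(times, function(tt)
        sum(vapply(long_tracks, function(tr)
          min(tr$time) <= tt && max(tr$time) >= tt, logical(1))), integer(1))
      n_conc_ps <- max(conc)
    }
  }
  if (!is.na(organized_from) && (is.null(ps_tracks) || n_conc_ps <= 1)) {
    return(structure(list(label = "AT",
                          event_time = (organized_from - t0) / 1000,
                          details = list(concurrent_long_ps = n_conc_ps)),
                     class = "af_outcome"))
  }
  structure(list(label = "AF", event_time = NA_real_,
                 details = list(concurrent_long_ps = n_conc_ps)),
            class = "af_outcome")
}

#' @export
print.af_outcome <- function(x, ...) {
  cat("<af_outcome> ", x$label,
      if (!is.na(x$event_time)) paste0(" (", round(x$event_time, 1), " s)"),
      "\n", sep = "")
  invisible(x)
}
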