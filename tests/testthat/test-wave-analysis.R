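# AP features, EAD detection, electrograms/CFAE, phase and phase
# singularities — each verified against its ground-truth fixture.

test_that("trapezoid AP recovers APD90/APD50 and diastolic potential", {
  fx <- make_fixture("trapezoid_ap")
  f <- extract_ap_features(fx$data, stim_times = 45, stim_dur = 0)
  expect_true(f$captured)
  expect_equal(f$v_diastolic, -80)
  expect_equal(f$v_peak, 20)
  expect_lt(abs(f$apd90 - fx$truth$apd90), 2)
  expect_lt(abs(f$apd50 - fx$truth$apd50), 2)
  expect_false(f$ead)
})

test_that("constant trace yields no captured beats", {
  tt <- seq(0, 1000, by = 1)
  f <- extract_ap_features(tt, rep(-80, length(tt)), stim_times = c(100, 600))
  expect_true(all(!f$captured))
  expect_true(all(is.na(f$apd90)))
})

test_that("EAD detector: monotone repolarization is negative, injected hump positive", {
  fx <- make_fixture("trapezoid_ap", ead_amp = 15, ead_at = -50)
  f <- extract_ap_features(fx$data, stim_times = 45, stim_dur = 0)
  expect_true(f$ead)
  expect_lt(abs(f$ead_takeoff - (-50)), 3)
  # sub-threshold hump stays negative
  fx2 <- make_fixture("trapezoid_ap", ead_amp = 6, ead_at = -50)
  f2 <- extract_ap_features(fx2$data, stim_times = 45, stim_dur = 0)
  expect_false(f2$ead)
  # hump outside the take-off window stays negative
  fx3 <- make_fixture("trapezoid_ap", ead_amp = 15, ead_at = -70)
  f3 <- extract_ap_features(fx3$data, stim_times = 45, stim_dur = 0)
  expect_false(f3$ead)
})

test_that("electrogram rejects common mode and counts planar passages", {
  fx <- make_fixture("planar_wave_movie", n_cycles = 3)
  d <- fx$data
  # uniform field: zero signal
  uni <- matrix(rep(sin(d$times / 50), each = nrow(d$maps)),
                nrow = nrow(d$maps))
  eg0 <- virtual_electrogram(uni, d$times, d$coords, node = 120)
  expect_lt(max(abs(eg0$signal)), 1e-9)
  # one biphasic deflection per passage
  eg <- virtual_electrogram(d$maps, d$times, d$coords, node = 120)
  defl <- detect_deflections(eg)
  expect_length(defl, 3)
  # doubling the wave frequency doubles the deflection count
  fx2 <- make_fixture("planar_wave_movie", n_cycles = 6, period = 75,
                      apd = 40)
  eg2 <- virtual_electrogram(fx2$data$maps, fx2$data$times, fx2$data$coords,
                             node = 120)
  expect_length(detect_deflections(eg2), 6)
})

test_that("CFAE-CL is exact on periodic trains and matches Poisson truth", {
  fx <- make_fixture("deflection_train", interval = 150)
  cc <- cfae_cl(fx$data)
  expect_true(cc$defined)
  expect_equal(cc$cl, fx$truth$cl, tolerance = 1e-6)
  # interval 100 ms -> node is inside the CFAE area at the 120-ms threshold
  fx100 <- make_fixture("deflection_train", interval = 100)
  expect_lte(cfae_cl(fx100$data)$cl, 120)
  expect_gt(cfae_cl(fx$data)$cl, 120)
  # Poisson train: estimator equals the generated truth; truth near 1/rate
  fxp <- make_fixture("deflection_train", mode = "poisson", rate = 1 / 80,
                      duration = 6000, seed = 5)
  ccp <- cfae_cl(fxp$data)
  expect_lt(abs(ccp$cl - fxp$truth$cl), 2)
  sem <- stats::sd(diff(fxp$truth$deflection_times)) /
    sqrt(length(fxp$truth$deflection_times) - 1)
  expect_lt(abs(fxp$truth$cl - 80), 4 * sem + 15)
  # fewer than two deflections is flagged undefined
  flat <- data.frame(time = 0:100, signal = rep(0, 101))
  expect_false(cfae_cl(flat)$defined)
})

test_that("phase of a sinusoid advances uniformly at the angular rate", {
  tt <- seq(0, 1000, by = 1)
  om <- 2 * pi / 200
  maps <- rbind(sin(om * tt), sin(om * tt))
  ph <- compute_phase(maps, tt, tau = 50, mean_window = Inf)  # quarter period
  dph <- diff(ph$phase[1, ])
  dph <- dph[abs(dph) < pi]  # drop wrap points
  expect_lt(max(abs(dph - om)), 0.02)
  # constant trace is flagged undefined
  ph2 <- compute_phase(rbind(rep(0, length(tt)), sin(om * tt)), tt, tau = 50)
  expect_false(ph2$valid[1])
  expect_true(all(is.na(ph2$phase[1, ])))
})

test_that("paced tissue phase winds 2*pi per pacing cycle", {
  dom <- tissue_grid(10, 10, 250, D = 0.1)
  r <- run_tissue(dom, stim_train(1:10, start = 10, period = 320, count = 4),
                  duration = 1300, map_every = 2)
  ph <- compute_phase(r$Vmap, r$map_times, tau = 10, mean_window = Inf)
  sel <- ph$times >= 330 & ph$times <= 330 + 3 * 320  # three full cycles
  for (node in c(1, 45, 100)) {
    w <- sum(atriagp:::wrap_pi(diff(ph$phase[node, sel])))
    expect_lt(abs(abs(w) / (3 * 2 * pi) - 1), 0.12)
  }
})

test_that("PS detection is exact on the analytic spiral and pair", {
  fx <- make_fixture("analytic_spiral", center = c(15.2, 15.3))
  for (f in seq_along(fx$data$times)) {
    d <- detect_phase_singularities(fx$data$phase[, , f])
    expect_identical(nrow(d), 1L)
    expect_identical(d$chirality, 1)
    expect_lt(abs(d$x - 15.2), 1)
    expect_lt(abs(d$y - 15.3), 1)
  }
  fx2 <- make_fixture("spiral_pair")
  d2 <- detect_phase_singularities(fx2$data$phase[, , 1])
  expect_identical(nrow(d2), 2L)
  expect_identical(sum(d2$chirality), 0)
  expect_identical(sort(d2$chirality), c(-1, 1))
})

test_that("uniform phase has no singularities; multirotor conserves total charge", {
  expect_identical(nrow(detect_phase_singularities(matrix(0.3, 20, 20))), 0L)
  fx <- make_fixture("chaotic_multirotor", n = 4, seed = 9)
  for (f in seq_along(fx$data$times)) {
    d <- detect_phase_singularities(fx$data$phase[, , f])
    # all seeded cores found near their generated positions
    expect_gte(nrow(d), 4)
    expect_identical(sum(d$chirality), sum(fx$truth$chirality))
    truth <- fx$truth$centers_by_frame[[f]]
    for (k in 1:4) {
      dist <- sqrt((d$x - truth[k, 1])^2 + (d$y - truth[k, 2])^2)
      expect_lt(min(dist), 2.5)
    }
  }
})

test_that("PS detection by winding matches a brute-force loop integral", {
  fx <- make_fixture("spiral_pair", c1 = c(10.2, 12.1), c2 = c(30.7, 17.9))
  ph <- fx$data$phase[, , 3]
  d <- detect_phase_singularities(ph)
  # brute force: winding of a radius-3 square loop
  loop_winding <- function(cx, cy, r = 3) {
    is <- c(seq(cx - r, cx + r), rep(cx + r, 2 * r), seq(cx + r, cx - r),
            rep(cx - r, 2 * r))
    js <- c(rep(cy - r, 2 * r), seq(cy - r, cy + r), rep(cy + r, 2 * r),
            seq(cy + r, cy - r))
    vals <- ph[cbind(is, js)]
    as.integer(round(sum(atriagp:::wrap_pi(diff(c(vals, vals[1])))) / (2 * pi)))
  }
  expect_identical(nrow(d), 2L)
  for (k in 1:2) {
    w <- loop_winding(round(d$x[k]), round(d$y[k]))
    expect_identical(w, as.integer(d$chirality[k]))
  }
  # loops far from both singularities have zero winding
  expect_identical(loop_winding(20, 25), 0L)
  expect_identical(loop_winding(35, 6), 0L)
})

test_that("PS tracking links stationary, parallel and meandering cores", {
  mk <- function(path, chir = 1) {
    do.call(rbind, lapply(seq_len(nrow(path)), function(f)
      data.frame(x = path[f, 1], y = path[f, 2], chirality = chir,
                 cell = 1, frame = f, time = f)))
  }
  stat <- mk(cbind(rep(5, 50), rep(5, 50)))
  tr <- track_ps(stat, max_hop = 2)
  expect_identical(tr$summary$count, 1L)
  expect_equal(tr$summary$mean_lifespan, 49)
  two <- rbind(mk(cbind(rep(5, 30), rep(5, 30)), 1),
               mk(cbind(rep(20, 30), rep(20, 30)), -1))
  tr2 <- track_ps(two, max_hop = 2)
  expect_identical(tr2$summary$count, 2L)
  set.seed(4)
  steps <- matrix(stats::rnorm(100, 0, 0.5), 50, 2)
  path <- apply(steps, 2, cumsum) + 10
  tr3 <- track_ps(mk(path), max_hop = 2)
  expect_identical(tr3$summary$count, 1L)
  rec <- as.matrix(tr3$tracks[[1]][, c("x", "y")])
  expect_lt(max(sqrt(rowSums((rec - path)^2))), 1e-9)
})
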