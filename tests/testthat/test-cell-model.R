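# Ionic-model correctness: oracle equivalence of the two independently
# coded right-hand sides, resting stability, gate kinetics, and the variant
# machinery.

test_that("reference and compiled derivative evaluations agree to 1e-9", {
  set.seed(42)
  for (k in 1:100) {
    s <- random_cell_state()
    v <- model_variant(gCaL_scale = runif(1, 0.5, 8),
                       gNCX_scale = runif(1, 0.5, 3),
                       gK1_scale = runif(1, 0.3, 1.6),
                       INa_inact_shift = runif(1, 0, 15),
                       ACh = runif(1, 0, 0.1))
    a <- crn_derivatives(s, v, istim = -10)
    b <- crn_rhs_cpp(unname(s), variant_par(v), istim = -10)
    expect_lt(max(abs(a$dstate - b$dstate) / (abs(a$dstate) + 1e-9)), 1e-9)
    expect_lt(max(abs(a$currents - b$currents) /
                    (abs(a$currents) + 1e-9)), 1e-9)
  }
})

test_that("unstimulated cell is quiescent and stays near rest for 10 s", {
  r <- simulate_cell(duration = 10000)
  s_end <- setNames(r$final_state[, 1], crn_state_names())
  expect_lt(abs(s_end["V"] - crn_initial_state()["V"]), 0.5)
  d <- crn_derivatives(s_end)
  expect_lt(abs(d$dstate[["V"]]), 0.01)
  # gates stay within [0,1] throughout (Rush-Larsen guarantees clip-free)
  expect_true(all(s_end[2:16] >= 0 & s_end[2:16] <= 1))
})

test_that("gate derivatives vanish at voltage-dependent steady state", {
  s <- crn_initial_state()
  for (V in c(-80, -40, 0, 20)) {
    s["V"] <- V
    g <- atriagp:::crn_gates(V)
    for (nm in names(g)) s[nm] <- g[[nm]]$inf
    d <- crn_derivatives(s)
    gd <- d$dstate[c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                     "d", "f", "w")]
    expect_lt(max(abs(gd)), 1e-12)
  }
})

test_that("identity variant reproduces the unmodified evaluation", {
  s <- random_cell_state()
  a <- crn_derivatives(s, model_variant())
  b <- crn_derivatives(s, apply_ans_stimulation(model_variant(), ACh = 0,
                                                ical_fold = 1, ncx_fold = 1,
                                                ina_shift_mV = 0))
  expect_identical(a$currents, b$currents)
})

test_that("blow-up and invalid states are reported with the field named", {
  s <- crn_initial_state()
  s["Cai"] <- -1
  expect_error(crn_derivatives(s), "Cai")
  s <- crn_initial_state()
  s["V"] <- NaN
  expect_error(crn_derivatives(s), "V")
})

test_that("IKACh obeys zero-dose, zero-driving-force and dose monotonicity", {
  expect_identical(ikach_current(-40, 0, -85), 0)
  expect_equal(ikach_current(-85, 0.05, -85), 0)
  i1 <- ikach_current(-40, 0.01, -85)
  i2 <- ikach_current(-40, 0.05, -85)
  expect_gt(i1, 0)
  expect_gt(i2, i1)
  # strictly increasing magnitude across a fine dose grid at fixed V > EK
  doses <- seq(0.005, 0.2, by = 0.005)
  vals <- ikach_current(-40, doses, -85)
  expect_true(all(diff(vals) > 0))
  expect_error(ikach_current(-40, -0.01, -85), "non-negative")
})

test_that("PV conversion is idempotent and uses the registry table", {
  f <- pv_factors()
  v <- apply_pv_variant(model_variant())
  expect_identical(v$region, "PV")
  expect_equal(v$gK1_scale, f$gK1_scale)
  expect_equal(v$gCaL_scale, f$gCaL_scale)
  expect_identical(apply_pv_variant(v), v)
})

test_that("AF remodeling scales K1/to/CaL/Kur and composes multiplicatively", {
  v <- apply_af_remodeling(model_variant())
  expect_equal(c(v$gK1_scale, v$gto_scale, v$gCaL_scale, v$gKur_scale),
               c(1.5, 0.2, 0.6, 0.5))
  expect_true(v$remodeled)
  v2 <- apply_af_remodeling(v)
  expect_equal(v2$gK1_scale, 1.5^2)
  expect_equal(v2$gto_scale, 0.2^2)
})

test_that("autonomic stimulation defaults match the combined condition", {
  v <- apply_ans_stimulation(model_variant())
  expect_equal(v$gCaL_scale, 7)
  expect_equal(v$gNCX_scale, 2)
  expect_equal(v$INa_inact_shift, 10)
  expect_equal(v$ACh, 0.05)
})

test_that("ICaL fold increases the peak L-type current during a paced beat", {
  run_peak <- function(v) {
    r <- simulate_cell(v, stim_times = 50, duration = 400, stim_amp = -25)
    min(probe_trace(r)$ICaL)  # inward: most negative value
  }
  p1 <- run_peak(model_variant())
  p7 <- run_peak(apply_ans_stimulation(model_variant(), ACh = 0,
                                       ical_fold = 7, ncx_fold = 1,
                                       ina_shift_mV = 0))
  expect_lt(p7, p1 * 2)  # at least twice as deep
})

test_that("APD orderings: ACh shortens, PV < LA, remodeled < control", {
  apd_la <- apd90_of(model_variant())
  apd_ach <- apd90_of(model_variant(ACh = 0.05))
  apd_pv <- apd90_of(apply_pv_variant(model_variant()))
  expect_true(is.finite(apd_la) && apd_la > 100)
  expect_lt(apd_ach, apd_la)
  expect_lt(apd_pv, apd_la)
  apd_ctrl500 <- apd90_of(model_variant(), pcl = 500)
  apd_remod500 <- apd90_of(apply_af_remodeling(model_variant()), pcl = 500)
  expect_lt(apd_remod500, apd_ctrl500)
})

test_that("variants serialize to YAML and back", {
  v <- apply_ans_stimulation(apply_pv_variant(model_variant()))
  y <- variant_to_yaml(v)
  v2 <- variant_from_yaml(text = y)
  expect_equal(v2[order(names(v2))], v[order(names(v))])
  expect_identical(variant_registry("ans_ead")$gCaL_scale, v$gCaL_scale)
})
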