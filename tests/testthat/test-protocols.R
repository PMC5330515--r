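# Protocol plumbing: ablation patterns, isolation verification, outcome
# classification, spontaneous-activation attribution.

test_that("stimulus trains validate their fields", {
  expect_error(stim_train(integer(0)), "nodes")
  expect_error(stim_train(1, period = 100, dur = 150), "dur")
})

test_that("ablation patterns cover the intended vertex sets", {
  g <- generate_idealized_la(subdiv = 3)
  lay <- generate_gp_octopus(g, seed = 2)
  gp_vts <- sort(unique(unlist(lapply(lay$gps, `[[`, "patch"))))
  p <- ablation_pattern(g, lay, "GP_ONLY")
  expect_identical(p$lesion, gp_vts)
  pw <- ablation_pattern(g, lay, "CPVI_WITH_GP")
  expect_true(all(gp_vts %in% pw$lesion))
  expect_true(verify_isolation(g, pw$lesion))
  po <- ablation_pattern(g, lay, "CPVI_WITHOUT_GP")
  expect_length(intersect(po$lesion, gp_vts), 0)
  expect_true(verify_isolation(g, po$lesion))
  # an open band (one ring vertex removed) is not isolating
  broken <- setdiff(po$lesion, po$lesion[seq(1, length(po$lesion), by = 4)])
  expect_false(verify_isolation(g, broken))
})

test_that("empty ablation leaves the domain unchanged; lesions clamp state", {
  g <- generate_idealized_la(subdiv = 2)
  dom <- la_tissue_domain(g)
  dom2 <- apply_ablation(dom, integer(0))
  expect_identical(dom2$lesion, dom$lesion)
  st <- matrix(crn_initial_state(), 21, dom$n)
  st[1, ] <- 0  # depolarized everywhere
  res <- apply_ablation(dom, c(3L, 7L), state = st)
  expect_true(all(res$domain$lesion[c(3, 7)]))
  expect_equal(res$state[1, 3], crn_initial_state()[["V"]])
})

test_that("CPVI prevents activations crossing from PV to the LA body", {
  g <- generate_idealized_la(subdiv = 3)
  lay <- generate_gp_octopus(g, seed = 2)
  dom <- la_tissue_domain(g)
  pat <- ablation_pattern(g, lay, "CPVI_WITH_GP")
  dom <- apply_ablation(dom, pat)
  site <- lspv_pacing_site(g)
  r <- run_tissue(dom, stim_train(site, start = 5, period = 1e9, count = 1,
                                  amp = -72),
                  duration = 500)
  counts <- activation_counts(r)
  la_body <- which(g$region == "LA" & !dom$lesion)
  expect_true(all(counts[la_body] == 0L))
  expect_gt(sum(counts[site]), 0)
})

test_that("outcome classifier labels its three fixture classes", {
  win <- c(0, 10000)
  quiet <- make_activation_fixture("quiet")
  o1 <- classify_outcome(quiet, win)
  expect_identical(o1$label, "Terminated")
  expect_lt(o1$event_time, 1)
  at <- make_activation_fixture("at", cl = 250)
  o2 <- classify_outcome(at, win)
  expect_identical(o2$label, "AT")
  af <- make_activation_fixture("af", cl = 250)
  o3 <- classify_outcome(af, win)
  expect_identical(o3$label, "AF")
  expect_true(is.na(o3$event_time))
})

test_that("classifier respects the concurrent-PS criterion when tracks are given", {
  at <- make_activation_fixture("at", cl = 250)
  # two simultaneous long-lived PSs -> not AT even with regular CLs
  mk <- function(x0, chir) do.call(rbind, lapply(1:40, function(f)
    data.frame(x = x0, y = 5, chirality = chir, cell = 1, frame = f,
               time = f * 100)))
  tracks <- track_ps(rbind(mk(3, 1), mk(20, -1)), max_hop = 1)
  o <- classify_outcome(at, c(0, 10000), ps_tracks = tracks,
                        long_lived_ms = 500)
  expect_identical(o$label, "AF")
})

test_that("spontaneous PV activations exclude stimulus-attributable beats", {
  g <- generate_idealized_la(subdiv = 2)
  pv_nodes <- which(grepl("^PV", as.character(g$region)))[1:3]
  fake <- list(
    activations = data.frame(node = rep(pv_nodes[1], 4),
                             time = c(7100, 8050, 9050, 9600)),
    stim_log = data.frame(time = c(8000, 9000), train = c(1, 1)))
  sp <- spontaneous_pv_activations(fake, g, t_from = 7000, t_to = 10000)
  expect_identical(sp$count, 2L)  # 7100 and 9600 are unattributed
  expect_setequal(sp$times, c(7100, 9600))
})

test_that("AF induction returns an explicit result either way", {
  g <- generate_idealized_la(subdiv = 2)
  lay <- generate_gp_octopus(g, seed = 1)
  r <- induce_af(g, lay, burst_pcls = c(150), burst_count = 4,
                 observe = 600, map_every = 5, seed = 1)
  expect_s3_class(r, "af_result")
  expect_type(r$induced, "logical")
  expect_gt(length(r$sim$map_times), 0)
})
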