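# Monodomain solver: diffusion-operator structure, splitting behaviour,
# boundary conditions, lesions, and conduction-velocity scaling.

test_that("diffusion operator annihilates constants and has the 5-point stencil", {
  dom <- tissue_grid(3, 3, dx = 1000, D = 0.2)  # dx = 1 mm
  L <- build_diffusion_operator(dom)
  expect_lt(max(abs(as.numeric(L %*% rep(3.7, 9)))), 1e-12)
  row <- as.numeric(L[5, ])
  expect_equal(row[5], -4 * 0.2)
  expect_equal(sort(row[c(2, 4, 6, 8)]), rep(0.2, 4))
  expect_equal(sum(row), 0)
})

test_that("cable operator spectrum matches the discrete-Laplacian closed form", {
  n <- 10
  dom <- tissue_grid(n, 1, dx = 500, D = 0.1)
  L <- build_diffusion_operator(dom)
  ev <- sort(eigen(as.matrix(L), only.values = TRUE)$values)
  dx <- 0.5
  analytic <- sort(-(2 * 0.1 / dx^2) * (1 - cos(pi * (0:(n - 1)) / n)))
  expect_equal(ev, analytic, tolerance = 1e-10)
})

test_that("zero diffusion reproduces the isolated single-cell trajectory bitwise", {
  v <- model_variant(ACh = 0.02)
  dom <- set_variants(tissue_grid(3, 3, 250, D = 0), v)
  stims <- stim_train(1:9, start = 20, period = 300, count = 2, amp = -25)
  r_sheet <- run_tissue(dom, stims, duration = 700, probes = 5,
                        probe_every = 0.5)
  r_cell <- simulate_cell(v, stim_times = c(20, 320), duration = 700,
                          stim_amp = -25)
  expect_identical(probe_trace(r_sheet)$V, probe_trace(r_cell)$V)
})

test_that("spatially uniform state without stimulus stays uniform", {
  dom <- tissue_grid(6, 6, 250, D = 0.1)
  r <- run_tissue(dom, list(), duration = 50, map_every = 25)
  expect_lt(max(apply(r$Vmap, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("same configuration twice gives identical output; duration 0 only the initial map", {
  dom <- tissue_grid(8, 8, 250, D = 0.1)
  st <- stim_train(1:8, start = 2, period = 1e9, count = 1)
  r1 <- run_tissue(dom, st, duration = 120, map_every = 10)
  r2 <- run_tissue(dom, st, duration = 120, map_every = 10)
  expect_identical(r1$Vmap, r2$Vmap)
  expect_identical(r1$activations, r2$activations)
  r0 <- run_tissue(dom, list(), duration = 0, map_every = 10)
  expect_identical(ncol(r0$Vmap), 1L)
})

test_that("single edge stimulus captures every node exactly once", {
  dom <- tissue_grid(20, 20, 250, D = 0.1)
  left <- which(rep(1:20, 20) == 1)
  r <- run_tissue(dom, stim_train(left, start = 5, period = 1e9, count = 1),
                  duration = 400)
  expect_true(all(activation_counts(r) == 1L))
})

test_that("planar conduction velocity scales as sqrt(D)", {
  cv1 <- cv_cached(0.05, dx = 100, dt = 0.005)
  cv2 <- cv_cached(0.2, dx = 100, dt = 0.005)
  expect_lt(abs(cv2 / cv1 - 2), 0.1)  # 2 +- 5%
})

test_that("default diffusion gives physiological planar CV", {
  cv <- cv_cached(default_diffusion())
  expect_gt(cv, 0.35)
  expect_lt(cv, 0.55)
})

test_that("after full repolarization all nodes return to rest (no boundary drift)", {
  dom <- tissue_grid(12, 12, 250, D = 0.1)
  r <- run_tissue(dom, stim_train(1:12, start = 5, period = 1e9, count = 1),
                  duration = 1500)
  v_end <- r$final_state[1, ]
  expect_lt(max(abs(v_end - crn_initial_state()["V"])), 1)
})

test_that("a full-width lesion line blocks conduction", {
  dom <- tissue_grid(20, 10, 250, D = 0.1)
  wall <- which(rep(1:20, 10) == 10)
  dom <- add_lesion(dom, wall)
  left <- which(rep(1:20, 10) == 1)
  r <- run_tissue(dom, stim_train(left, start = 5, period = 1e9, count = 1),
                  duration = 400)
  distal <- which(rep(1:20, 10) > 10)
  expect_true(all(activation_counts(r)[distal] == 0L))
  proximal <- which(rep(1:20, 10) < 10)
  expect_true(all(activation_counts(r)[proximal] == 1L))
})

test_that("flat triangulated sheet conducts within 10% of the equivalent grid", {
  nx <- 40; ny <- 5; dx <- 0.25
  cv_grid <- measure_planar_cv(tissue_grid(nx, ny, 250, D = 0.1))
  # same lattice, split into right triangles
  xs <- rep((seq_len(nx) - 1) * dx, ny)
  ys <- rep((seq_len(ny) - 1) * dx, each = nx)
  vtx <- cbind(xs, ys, 0)
  tri <- NULL
  idx <- function(i, j) i + (j - 1) * nx
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    tri <- rbind(tri, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  mdom <- tissue_mesh(vtx, tri, D = 0.1)
  leftv <- which(xs == 0)
  r <- run_tissue(mdom, stim_train(leftv, start = 5, period = 1e9, count = 1, amp = -80),
                  duration = 60)
  a <- r$activations
  mid <- which(ys == 2 * dx)
  n1 <- mid[which.min(abs(xs[mid] - 0.25 * nx * dx))]
  n2 <- mid[which.min(abs(xs[mid] - 0.75 * nx * dx))]
  t1 <- a$time[a$node == n1][1]; t2 <- a$time[a$node == n2][1]
  cv_mesh <- (xs[n2] - xs[n1]) / (t2 - t1)
  expect_lt(abs(cv_mesh - cv_grid) / cv_grid, 0.1)
})

test_that("degenerate triangles are rejected with their indices", {
  vtx <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(1, 1, 0))
  tri <- rbind(c(1, 2, 3), c(1, 2, 4))  # first is collinear
  dom <- tissue_mesh(vtx, tri)
  expect_error(build_diffusion_operator(dom), "degenerate")
})

test_that("step budget is enforced", {
  dom <- tissue_grid(2, 2, 250)
  expect_error(run_tissue(dom, list(), duration = 1e9, dt = 0.02),
               "step budget")
})
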