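# Idealized LA shell, GP/nerve layout and area overlap.

test_that("default LA shell has 5 named boundary loops, 4 PV regions, chi = -3", {
  g <- generate_idealized_la(subdiv = 3)
  expect_length(g$loops, 5)
  expect_setequal(names(g$loops), c("PV1", "PV2", "PV3", "PV4", "mitral"))
  expect_setequal(intersect(levels(g$region), unique(as.character(g$region))),
                  c("LA", "PV1", "PV2", "PV3", "PV4", "BachmannSite"))
  expect_identical(euler_characteristic(g), -3L)
})

test_that("doubling the resolution quadruples the triangle count within 20%", {
  g3 <- generate_idealized_la(subdiv = 3)
  g4 <- generate_idealized_la(subdiv = 4)
  ratio <- nrow(g4$triangles) / nrow(g3$triangles)
  expect_lt(abs(ratio - 4) / 4, 0.2)
})

test_that("overlapping openings are rejected", {
  expect_error(generate_idealized_la(subdiv = 3, pv_theta = 40),
               "infeasible ostium placement")
})

test_that("ACh field support equals GP plus nerves and scales with nerve length", {
  g <- generate_idealized_la(subdiv = 3)
  lay <- generate_gp_octopus(g, ach = 0.05, seed = 3)
  on <- which(lay$ach > 0)
  member <- sort(unique(unlist(lapply(lay$gps, function(gp)
    c(gp$patch, gp$nerve_vertices, unlist(gp$nerves))))))
  expect_setequal(on, member)
  expect_true(all(lay$ach[on] == 0.05))

  lay0 <- generate_gp_octopus(g, n_nerves_per_gp = 0, seed = 3)
  patches <- sort(unique(unlist(lapply(lay0$gps, `[[`, "patch"))))
  expect_setequal(which(lay0$ach > 0), patches)

  fr <- vapply(c(5, 12, 20), function(L)
    mean(generate_gp_octopus(g, nerve_length = L, seed = 3)$ach > 0),
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("GP layout is deterministic under a fixed seed and patches are disjoint", {
  g <- generate_idealized_la(subdiv = 3)
  a <- generate_gp_octopus(g, seed = 11)
  b <- generate_gp_octopus(g, seed = 11)
  expect_identical(a$ach, b$ach)
  patches <- lapply(a$gps, `[[`, "patch")
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(patches[[i]], patches[[j]]), 0)
})

test_that("area overlap: identity 100%, disjoint 0%, analytic half-split ~50%", {
  g <- generate_idealized_la(subdiv = 3)
  la <- which(g$region == "LA")
  expect_equal(label_overlap(la, la, g), 100)
  expect_equal(label_overlap(which(g$region == "PV1"),
                             which(g$region == "PV2"), g), 0)
  # split the whole shell at the median x: overlap of all with one half
  all_v <- seq_len(nrow(g$vertices))
  half <- which(g$vertices[, 1] <= stats::median(g$vertices[, 1]))
  ov <- label_overlap(all_v, half, g)
  expect_lt(abs(ov - 50), 3)
})

test_that("mesh I/O round-trips through OBJ and writes valid VTK", {
  g <- generate_idealized_la(subdiv = 2)
  p <- tempfile(fileext = ".obj")
  write_obj(g, p)
  m <- read_obj(p)
  expect_equal(m$vertices, unname(g$vertices), tolerance = 1e-5)
  expect_identical(m$triangles, unname(g$triangles))
  pv <- tempfile(fileext = ".vtk")
  write_vtk(g, pv, point_data = list(region = as.integer(g$region)))
  ln <- readLines(pv)
  expect_identical(ln[4], "DATASET POLYDATA")
  expect_true(any(grepl("^SCALARS region", ln)))
})
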