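# Configuration validation, provenance hashing and orchestration.

test_that("unknown configuration keys are rejected; hash is stable", {
  expect_error(experiment_config(protocol = list(kind = "ead2d"),
                                 bogus = 1), "unknown configuration keys")
  expect_error(experiment_config(name = "x"), "protocol")
  a <- experiment_config(protocol = list(kind = "ead2d"), seed = 3)
  b <- experiment_config(protocol = list(kind = "ead2d"), seed = 3)
  c <- experiment_config(protocol = list(kind = "ead2d"), seed = 4)
  expect_identical(a$hash, b$hash)
  expect_false(identical(a$hash, c$hash))
})

test_that("missing configuration file raises a clear error naming the path", {
  expect_error(read_experiment_config("/no/such/config.yaml"),
               "/no/such/config.yaml")
})

test_that("a small 2D experiment runs end-to-end and writes its manifest", {
  out <- tempfile("exp")
  cfg <- experiment_config(
    name = "mini", seed = 2, out_dir = out,
    protocol = list(kind = "ead2d", n_fast = 3, n_slow = 2,
                    first_pcl = 150, second_pcl = 400, nx = 6, ny = 6))
  res <- run_experiment(cfg)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "probe_trace.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$hash, cfg$hash)
  expect_type(res$summary$diastolic_end_pacing, "double")
  # identical config -> identical simulated summary
  res2 <- run_experiment(cfg)
  expect_identical(res$summary, res2$summary)
})
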