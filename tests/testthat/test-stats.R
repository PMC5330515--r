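# Paired comparisons and their degenerate cases.

test_that("identical inputs flag both tests as degenerate", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_paired(x, x)
  expect_true(any(grepl("degenerate_t", r$flags)))
  expect_true(any(grepl("degenerate_wilcoxon", r$flags)))
  expect_identical(r$mean_diff, 0)
})

test_that("constant shift gives the exact difference and a degenerate t", {
  y <- rnorm(10)
  r <- compare_paired(y + 2.5, y)
  expect_equal(r$mean_diff, 2.5)
  expect_identical(r$sd_diff, 0)
  expect_true(any(grepl("degenerate_t", r$flags)))
  expect_false(is.na(r$wilcoxon_p))
})

test_that("paired t p-value matches the closed form to 1e-10", {
  set.seed(123)
  y <- rnorm(10)
  x <- y + rnorm(10, 0.5, 1)
  r <- compare_paired(x, y)
  d <- x - y
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_closed <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  expect_lt(abs(r$t_p - p_closed), 1e-10)
})

test_that("input contracts are enforced", {
  expect_error(compare_paired(1, 1), "at least 2")
  expect_error(compare_paired(1:3, 1:4), "equal length")
})

test_that("categorical comparison returns both tests", {
  tab <- matrix(c(6, 4, 0, 10), 2)
  r <- compare_categorical(tab)
  expect_true(r$fisher_p < 0.05)
  expect_true(is.finite(r$chisq_p))
})
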