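test_that("binarization follows the boundary convention and is monotone in theta", {
  expect_identical(as.integer(binarize(c(0.1, 0.5, 0.9), 0.5)), c(0L, 1L, 1L))
  expect_error(binarize(c(0.1, 0.2), 0), "theta")
  expect_error(binarize(c(0.1, 0.2), 1), "theta")
  expect_identical(as.integer(binarize(rep(0.3, 5), 0.5)), rep(0L, 5))

  set.seed(31)
  pr <- runif(2000)
  for (i in 1:10) {
    th <- sort(runif(2, 0.05, 0.95))
    lo <- binarize(pr, th[1]); hi <- binarize(pr, th[2])
    expect_true(all(hi <= lo))  # raising theta only turns 1s into 0s
  }
})

test_that("binarization of the reflected train is the bitwise complement", {
  set.seed(32)
  theta <- 0.5; eps <- 1e-9
  pr <- runif(5000)
  pr <- pr[pr < theta - eps | pr >= theta]
  a <- binarize(pr, theta)
  b <- binarize(1 - pr, 1 - theta + eps)
  expect_identical(as.integer(b), 1L - as.integer(a))
})

test_that("histograms are normalized frequency distributions on even bins", {
  h <- pr_histogram(rep(0.42, 100), 50)
  expect_equal(sum(h$freqs), 1)
  expect_identical(sum(h$freqs > 0), 1L)
  expect_equal(max(h$freqs), 1)

  set.seed(33)
  hu <- pr_histogram(runif(1e5), 50)
  expect_true(all(abs(hu$freqs - 0.02) < 0.003))
  expect_error(pr_histogram(numeric(0)), "empty")
  expect_error(pr_histogram(runif(10), 1), "n_bins")
})

test_that("entropy in bits matches hand-computed values", {
  expect_equal(entropy_bits(c(1)), 0)
  expect_equal(entropy_bits(rep(1 / 8, 8)), 3)
  expect_equal(entropy_bits(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(entropy_bits(pr_histogram(rep(0.9, 10))), 0)
  expect_error(entropy_bits(c(0.5, 0.2)), "sum to 1")
})

test_that("threshold selection maximizes complexity over robust candidates", {
  pr <- rep(c(0.2, 0.8), 3000)
  sel <- select_threshold(pr)
  expect_equal(sel$cmu_bits, 1)
  expect_identical(n_states(sel$machine), 2L)
  expect_true(sel$theta > 0.2 && sel$theta <= 0.8)
  # the reported complexity dominates every robust candidate on the grid
  if (!is.null(sel$sweep))
    expect_true(all(sel$cmu_bits >= sel$sweep$cmu_bits[
      fdmachine:::robust_candidates(attr(sel$sweep, "machines"))] - 1e-9))
})

test_that("the narrow-support guard falls back to the support midpoint", {
  set.seed(34)
  pr <- 0.4 + 0.05 * runif(5000)     # one narrow mode, width << 0.2
  sel <- select_threshold(pr)
  expect_identical(sel$fallback, "narrow-support")
  expect_identical(n_states(sel$machine), 1L)
  expect_equal(sel$theta, mean(quantile(pr, c(0.005, 0.995))),
               tolerance = 1e-10)
  expect_error(select_threshold(rep(0.5, 5000)), "narrow-support")
  expect_error(select_threshold(runif(10)), "1000")
})

test_that("threshold sweeps expose topology robustness over the grid", {
  set.seed(35)
  pr <- rep(c(0.2, 0.8), 2500) + rnorm(5000, 0, 0.02)
  sw <- threshold_sweep(pr, seq(0.3, 0.7, by = 0.1))
  expect_identical(nrow(sw), 5L)
  expect_true(all(sw$n_states == 2L))
  ms <- attr(sw, "machines")
  expect_true(all(vapply(seq_len(4), function(i)
    topologically_equal(ms[[i]], ms[[i + 1]]), logical(1))))
})

test_that("symbol streams serialize as plain 0/1 text", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_symbols(binarize(c(0.1, 0.9, 0.9), 0.5), path)
  expect_identical(readLines(path), "011")
})
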