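test_that("the two-component system is solved algebraically", {
  # mixture of two equal components: donor channel values chosen so that
  # substituting back gives (1000, 1000)
  sol <- solve_two_component(s_dd_on = 2000, s_dd_off = 1300,
                             s_da_on = 2000, s_da_off = 1300,
                             rho_d1 = 0.3, rho_d2 = 1.0,
                             rho_a1 = 0.3, rho_a2 = 1.0)
  expect_equal(sol$s_dd_on, c(1000, 1000))

  # single-species limit: pair 2 absent
  sol2 <- solve_two_component(500, 150, 500, 150, 0.3, 1.0, 0.3, 1.0)
  expect_equal(sol2$s_dd_on, c(500, 0))
})

test_that("near-singular channels raise an unresolvable-pairs error naming the channel", {
  expect_error(solve_two_component(100, 50, 100, 50, 0.5, 0.5, 0.3, 1.0),
               regexp = "donor", class = "pcfret_unresolvable")
  expect_error(solve_two_component(100, 50, 100, 50, 0.3, 1.0, 0.5, 0.51),
               regexp = "acceptor", class = "pcfret_unresolvable")
})

test_that("the n-component ladder solve reduces to the two-component case", {
  rho <- rbind(c(1, 1), c(0.3, 1.0))
  s <- c(2000, 1300)
  xn <- solve_n_component(s, rho)
  x2 <- solve_two_component(2000, 1300, 2000, 1300, 0.3, 1.0, 0.3, 1.0)
  expect_equal(as.numeric(xn), x2$s_dd_on)
})

test_that("three pairs are recovered exactly from a noiseless ladder", {
  # retention vectors per pair across the 3 acquisitions (on + 2 offs)
  rho <- cbind(c(1, 0.5, 0.25), c(1, 0.9, 0.81), c(1, 1, 1))
  truth <- c(100, 200, 300)
  # hand-computed signals: rho %*% truth
  signals <- c(100 + 200 + 300,
               0.5 * 100 + 0.9 * 200 + 300,
               0.25 * 100 + 0.81 * 200 + 300)
  x <- solve_n_component(signals, rho)
  expect_equal(as.numeric(x), truth, tolerance = 1e-12)
  expect_true(is.finite(attr(x, "condition_number")))
})

test_that("rank-deficient ladders and malformed inputs are rejected", {
  rho_dup <- cbind(c(1, 0.5, 0.25), c(1, 0.5, 0.25), c(1, 1, 1))
  expect_error(solve_n_component(c(3, 2, 1), rho_dup),
               class = "pcfret_unresolvable")
  expect_error(solve_n_component(c(3, 2), cbind(c(0.9, 1), c(1, 1))),
               class = "pcfret_invalid_input")
})

test_that("noiseless mixtures are inverted to machine-level accuracy", {
  pairs <- two_pair_models()
  acq <- noiseless_acq(c(0.35, 0.10), n = 10000)
  res <- iterative_unmix(acq$on, acq$off, pairs)
  expect_true(attr(res, "converged"))
  expect_lte(attr(res, "iterations"), 20)
  expect_lt(mad_theta(c(0.35, 0.10), res$theta), 1e-6)
})

test_that("a pure single pair reduces to single-sensor FRET analysis", {
  pairs <- two_pair_models()
  acq <- simulate_acquisition(list(pair_sim_spec(8000, 0.3),
                                   pair_sim_spec(0, 1.0)),
                              c(0.25, 0), noise = FALSE)
  res <- iterative_unmix(acq$on, acq$off, pairs)
  expect_equal(res$s_dd_on[2], 0, tolerance = 1e-9)
  expect_equal(res$s_da_on[2], 0, tolerance = 1e-9)
  single <- as.numeric(suppressWarnings(
    fret_efficiency(acq$on$s_da, acq$on$s_dd, gamma = 1)))
  expect_equal(res$theta[1], single, tolerance = 1e-9)
})

test_that("two photostatic pairs are unresolvable", {
  pairs <- two_pair_models(rho0 = c(1.0, 1.0))
  acq <- noiseless_acq(c(0.3, 0.1), rho0 = c(1.0, 1.0))
  expect_error(iterative_unmix(acq$on, acq$off, pairs),
               class = "pcfret_unresolvable")
})

test_that("unmixing is symmetric under swapping the pair labels", {
  pairs <- two_pair_models()
  acq <- noiseless_acq(c(0.45, 0.05))
  res <- iterative_unmix(acq$on, acq$off, pairs)

  pairs_sw <- list(pairs[[2]], pairs[[1]])
  acq_sw <- noiseless_acq(c(0.05, 0.45), rho0 = c(1.0, 0.3))
  res_sw <- iterative_unmix(acq_sw$on, acq_sw$off, pairs_sw)
  expect_equal(res_sw$theta, rev(res$theta), tolerance = 1e-9)
  expect_equal(res_sw$s_dd_on, rev(res$s_dd_on), tolerance = 1e-9)
})

test_that("the fixed point is independent of the starting guess", {
  pairs <- two_pair_models()
  acq <- noiseless_acq(c(0.42, 0.17))
  ref <- iterative_unmix(acq$on, acq$off, pairs)$theta
  set.seed(3)
  starts <- matrix(runif(50, 0, 0.6), ncol = 2)
  for (i in seq_len(nrow(starts))) {
    res <- iterative_unmix(acq$on, acq$off, pairs, init = starts[i, ])
    expect_equal(res$theta, ref, tolerance = 1e-5)
  }
})

test_that("recovered components always sum to the measured mixture", {
  pairs <- two_pair_models()
  specs <- two_pair_specs(n = 800)
  set.seed(5)
  for (i in 1:40) {
    th <- runif(2, 0, 0.6)
    acq <- simulate_acquisition(specs, th)
    res <- tryCatch(iterative_unmix(acq$on, acq$off, pairs),
                    pcfret_error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(sum(res$s_dd_on), acq$on$s_dd,
                 tolerance = 1e-9 * max(acq$on$s_dd, 1))
    expect_equal(sum(res$s_da_on), acq$on$s_da,
                 tolerance = 1e-9 * max(acq$on$s_da, 1))
  }
})

test_that("negative components under noise are clipped and flagged", {
  pairs <- two_pair_models()
  # pair 2 truly absent; noise will push its recovered share negative in
  # roughly half the draws
  specs <- list(pair_sim_spec(500, 0.3), pair_sim_spec(0, 1.0))
  hits <- 0L
  for (seed in 1:30) {
    acq <- simulate_acquisition(specs, c(0.3, 0), seed = seed)
    res <- tryCatch(iterative_unmix(acq$on, acq$off, pairs),
                    pcfret_error = function(e) NULL)
    if (is.null(res)) next
    expect_true(all(res$s_dd_on >= 0))
    expect_true(all(res$s_da_on >= 0))
    if (any(res$clipped)) hits <- hits + 1L
  }
  expect_gt(hits, 0L)
})

test_that("time-series unmixing warm-starts and tracks step changes", {
  pairs <- two_pair_models()
  # constant-signal trace gives constant efficiency traces
  acq <- noiseless_acq(c(0.3, 0.2))
  n_t <- 5
  trace <- data.frame(
    time_s = as.vector(rbind((0:(n_t - 1)) * 30, (0:(n_t - 1)) * 30 + 1)),
    state = rep(c("on", "off"), n_t),
    s_dd = rep(c(acq$on$s_dd, acq$off$s_dd), n_t),
    s_da = rep(c(acq$on$s_da, acq$off$s_da), n_t),
    s_aa = NA_real_)
  res <- unmix_timeseries(trace, pairs)
  expect_equal(nrow(res), 2 * n_t)
  for (p in c("pair1", "pair2")) {
    expect_lt(diff(range(res$theta[res$pair_id == p])), 1e-9)
  }

  # step change in pair 1 only leaves the pair-2 trace flat
  th1 <- c(0.1, 0.1, 0.4, 0.4)
  rows <- lapply(seq_along(th1), function(k) {
    a <- noiseless_acq(c(th1[k], 0.2))
    data.frame(time_s = c((k - 1) * 30, (k - 1) * 30 + 1),
               state = c("on", "off"),
               s_dd = c(a$on$s_dd, a$off$s_dd),
               s_da = c(a$on$s_da, a$off$s_da), s_aa = NA_real_)
  })
  res2 <- unmix_timeseries(do.call(rbind, rows), pairs)
  t2 <- res2$theta[res2$pair_id == "pair2"]
  t1 <- res2$theta[res2$pair_id == "pair1"]
  expect_lt(diff(range(t2)), 1e-6)
  expect_equal(t1, th1, tolerance = 1e-6)

  # empty trace gives an empty result
  empty <- trace[0, ]
  expect_equal(nrow(unmix_timeseries(empty, pairs)), 0)
})

test_that("grid-search unmixing agrees with the iterative solver", {
  pairs <- two_pair_models()
  grid <- seq(0, 0.6, length.out = 61)
  for (th in list(c(0.35, 0.10), c(0.05, 0.55), c(0.2, 0.2))) {
    acq <- noiseless_acq(th, n = 5000)
    it <- iterative_unmix(acq$on, acq$off, pairs)$theta
    gs <- unmix_grid_search(acq$on, acq$off, pairs, grid = grid)$theta
    expect_lt(max(abs(gs - it)), diff(grid[1:2]) + 1e-9)
  }
})

test_that("a dark-acceptor pair contributes nothing to the acceptor channel", {
  dark <- pair_model("dark",
                     calibration_model("power_law", c(rho0 = 0.3),
                                       valid_range = c(0, 0.6)),
                     acceptor_cal = NULL)
  bright <- two_pair_models()[[2]]
  # dark pair: donor signal only (theta = 0 contribution in s_da)
  acq_on <- fret_acquisition(s_dd = 1000 + 900, s_da = 100, state = "on")
  acq_off <- fret_acquisition(s_dd = 0.3 * 1000 + 900, s_da = 100,
                              state = "off")
  res <- iterative_unmix(acq_on, acq_off, list(dark, bright))
  expect_equal(res$s_dd_on[1], 1000, tolerance = 1e-6)
  expect_equal(res$s_da_on[1], 0, tolerance = 1e-6)
})
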