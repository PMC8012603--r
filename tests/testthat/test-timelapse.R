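planted_sigmoid <- function(t, A, t0, r) A / (1 + exp((t0 - t) / r))

test_that("ROI traces are background-corrected mean intensities", {
  # uniform image value v over cells, background value b
  img <- matrix(3, 10, 10)
  rois <- matrix(0L, 10, 10); rois[2:4, 2:4] <- 1L
  img[rois == 1L] <- 10
  bg <- rois == 0L
  stack <- array(img, c(10, 10, 4))
  tr <- extract_roi_traces(stack, rois, bg)
  expect_equal(tr[["1"]]$value, rep(7, 4))

  # background equal to the image gives a zero trace
  tr0 <- extract_roi_traces(array(3, c(10, 10, 2)), rois, bg)
  expect_equal(tr0[["1"]]$value, rep(0, 2))

  # negative corrected intensities are floored at zero and flagged
  dim_img <- matrix(5, 10, 10); dim_img[rois == 1L] <- 2
  trn <- extract_roi_traces(array(dim_img, c(10, 10, 1)), rois, bg)
  expect_equal(trn[["1"]]$value, 0)
  expect_true(trn[["1"]]$flag)
})

test_that("ROI extraction validates masks and frames", {
  rois <- matrix(0L, 8, 8); rois[2:3, 2:3] <- 1L
  stack <- array(1, c(8, 8, 2))
  expect_error(extract_roi_traces(stack, rois, matrix(FALSE, 8, 8)),
               class = "pcfret_empty_roi")
  overlap <- matrix(TRUE, 8, 8)
  expect_error(extract_roi_traces(stack, rois, overlap),
               class = "pcfret_invalid_input")
  expect_error(extract_roi_traces(stack, rois, rois == 0L, time = 1),
               class = "pcfret_missing_frames")
})

test_that("fixture stacks reproduce their planted per-ROI means exactly", {
  sp <- fixture_spec(dim = c(32, 32),
                     cells = data.frame(row = 16, col = 16, radius = 6),
                     theta1 = rbind(c(0.1, 0.3)), theta2 = rbind(c(0.2, 0.2)),
                     brightness = 1000, bg_level = 5, noise = "none")
  fx <- generate_fixture(sp)
  tr <- extract_roi_traces(fx$stacks$dd_on, fx$rois, fx$background,
                           time = fx$time)
  expected <- 1000 * (1 - 0.1) + 1000 * (1 - 0.2)
  expect_equal(tr[["1"]]$value[1], expected, tolerance = 1e-12)
})

test_that("the bleaching-times-sigmoid baseline fit recovers planted parameters", {
  truth <- c(tau = 1e4, b = 0.2, A = 0.1, t0 = 600, r = 30)
  t <- seq(0, 3600, by = 15)
  y <- exp(-t / truth["tau"]) *
    (truth["b"] + planted_sigmoid(t, truth["A"], truth["t0"], truth["r"]))
  set.seed(21)
  yn <- y * (1 + rnorm(length(y), 0, 0.01))
  fit <- fit_baseline(cell_trace(t, yn), "sigmoid_exp")
  for (p in names(truth)) {
    expect_lt(abs(fit$params[[p]] - truth[[p]]) / truth[[p]], 0.05)
  }
  # the baseline is the decay-only factor
  expect_equal(fit$baseline(0), fit$params[["b"]])
})

test_that("a flat trace yields a flat baseline with negligible response", {
  t <- seq(0, 1200, by = 20)
  fit <- fit_baseline(cell_trace(t, rep(0.25, length(t))), "sigmoid_exp")
  expect_equal(fit$baseline(t), rep(0.25, length(t)), tolerance = 1e-3)
  expect_lt(fit$params[["A"]], 1e-6)
})

test_that("zero response amplitude reduces the model to the bare baseline", {
  t <- seq(0, 1200, by = 20)
  y <- 0.3 * exp(-t / 5000)
  fit <- fit_baseline(cell_trace(t, y), "sigmoid_exp")
  expect_equal(fit$model(t), fit$baseline(t), tolerance = 1e-6)
  expect_equal(fit$baseline(t), y, tolerance = 1e-4)
})

test_that("biexponential baselines are fitted on quiet intervals only", {
  t <- seq(0, 2000, by = 10)
  base <- 400 * exp(-t / 3000) + 100 * exp(-t / 500)
  y <- base + ifelse(t >= 800 & t < 1200,
                     300 * exp(-(t - 800) / 100), 0)  # calcium transient
  fit <- fit_baseline(cell_trace(t, y), "biexponential",
                      quiet_intervals = list(c(0, 800), c(1300, 2000)))
  expect_equal(fit$baseline(t), base, tolerance = 0.01 * max(base))
  expect_error(fit_baseline(cell_trace(t, y), "biexponential"),
               class = "pcfret_invalid_input")
})

test_that("short traces are rejected for baseline fitting", {
  expect_error(fit_baseline(cell_trace(1:5, rnorm(5)), "sigmoid_exp"),
               class = "pcfret_invalid_input")
})

test_that("percent increase is the relative excursion above baseline", {
  t <- seq(0, 100, by = 10)
  tr <- cell_trace(t, rep(0.4, length(t)))
  expect_equal(percent_increase(tr, rep(0.4, length(t)))$value,
               rep(0, length(t)))
  expect_equal(percent_increase(tr, rep(0.4 / 1.5, length(t)))$value,
               rep(50, length(t)))
  expect_error(percent_increase(tr, rep(0, length(t))),
               class = "pcfret_invalid_input")

  # invariance under joint rescaling of signal and baseline
  tr2 <- cell_trace(t, 7.3 * tr$value)
  expect_equal(percent_increase(tr2, 7.3 * rep(0.3, length(t)))$value,
               percent_increase(tr, rep(0.3, length(t)))$value)
})

test_that("maximum response uses the half-open interval and keeps its sign", {
  t <- seq(0, 90, by = 10)
  ramp <- cell_trace(t, seq(0, 30, length.out = length(t)))
  expect_equal(max_response(ramp, c(0, 91)), 30)
  # t = 90 is excluded from [0, 90)
  expect_equal(max_response(ramp, c(0, 90)), ramp$value[length(t) - 1])
  neg <- cell_trace(t, seq(-40, -10, length.out = length(t)))
  expect_equal(max_response(neg, c(0, 91)), -10)
  expect_error(max_response(ramp, c(200, 300)), class = "pcfret_invalid_input")
})

test_that("sigmoid onset matches the analytic 7.6%-of-maximum inversion", {
  t <- seq(0, 300, by = 2)
  resp <- cell_trace(t, planted_sigmoid(t, A = 50, t0 = 100, r = 10))
  analytic <- 100 - 10 * log(1 / 0.076 - 1)  # ~75.0 s
  expect_lt(abs(onset_time(resp, "sigmoid_7p6") - analytic), 1)
})

test_that("onset estimates shift with a time-shifted response", {
  t <- seq(0, 600, by = 5)
  y <- planted_sigmoid(t, A = 40, t0 = 200, r = 15)
  base <- onset_time(cell_trace(t, y), "sigmoid_7p6")
  shifted <- onset_time(cell_trace(t + 130, y), "sigmoid_7p6")
  expect_equal(shifted - base, 130, tolerance = 0.5)

  base2 <- onset_time(cell_trace(t, y), "second_derivative")
  shifted2 <- onset_time(cell_trace(t + 130, y), "second_derivative")
  expect_equal(shifted2 - base2, 130, tolerance = 5 + 1e-9)
})

test_that("the smoothed second derivative peaks at the foot of the rise", {
  t <- seq(0, 600, by = 5)
  y <- planted_sigmoid(t, A = 40, t0 = 300, r = 20)
  onset <- onset_time(cell_trace(t, y), "second_derivative")
  # analytic argmax of the sigmoid's second derivative: t0 - r*log(2 + sqrt(3))
  expect_equal(onset, 300 - 20 * log(2 + sqrt(3)), tolerance = 10)
})

test_that("flat responses yield an absent onset with a flag", {
  t <- seq(0, 100, by = 5)
  res <- onset_time(cell_trace(t, rep(1, length(t))), "sigmoid_7p6")
  expect_true(is.na(res))
  expect_identical(attr(res, "flag"), "no_rise")
  res2 <- onset_time(cell_trace(t, rep(1, length(t))), "second_derivative")
  expect_true(is.na(res2))
})

test_that("k-means response classification recovers planted classes", {
  set.seed(8)
  centers <- rbind(c(0, 0, 0), c(10, 0, 5), c(0, 10, -5))
  planted <- rep(1:3, times = c(20, 15, 10))
  feats <- centers[planted, ] + matrix(rnorm(45 * 3, 0, 0.3), ncol = 3)
  lab <- cluster_responses(feats, k = 3, seed = 1)
  # perfect recovery up to permutation
  expect_equal(length(unique(lab)), 3)
  tab <- table(planted, lab)
  expect_equal(sum(apply(tab, 1, max)), 45)
  # canonical order: label 1 is the largest class
  expect_equal(as.integer(which.max(table(lab))), 1L)
})

test_that("degenerate clustering inputs are handled canonically", {
  feats <- matrix(1, nrow = 6, ncol = 2)
  lab <- cluster_responses(feats, k = 3)
  expect_equal(lab, rep(1L, 6))  # one effective cluster
  expect_equal(cluster_responses(matrix(rnorm(10), 5), k = 1), rep(1L, 5))
  expect_error(cluster_responses(matrix(rnorm(4), 2), k = 3),
               class = "pcfret_invalid_input")
})
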