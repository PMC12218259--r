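test_that("low-pass design meets its passband and stopband specification", {
  b <- design_lowpass(pass = 0.5, stop = 0.65, ripple_db = 1, atten_db = 25)
  ## frequency-response oracle: evaluate the realized response directly
  w_pass <- seq(0, 0.5, by = 0.01)
  w_stop <- seq(0.65, 1, by = 0.01)
  hp <- 20 * log10(abs(filter_response(b, w_pass)))
  hs <- 20 * log10(abs(filter_response(b, w_stop)))
  expect_lt(max(abs(hp)), 1 + 1e-9)
  expect_lt(max(hs), -25 + 1e-9)
  expect_error(design_lowpass(pass = 0.6, stop = 0.601, atten_db = 80),
               "could not meet")
})

test_that("filtering preserves DC and attenuates stopband sinusoids", {
  b <- design_lowpass()
  dc <- matrix(1, 1, 400)
  y <- lowpass_filter(dc, b)
  expect_true(all(abs(y[1, 100:300] - 1) < 0.12))   # within ripple
  ## 0.8 x Nyquist sinusoid: amplitude down by >= 25 dB
  t <- seq_len(2000)
  x <- matrix(sin(pi * 0.8 * t), 1)
  y <- lowpass_filter(x, b)
  gain <- sqrt(mean(y[1, 200:1800]^2)) / sqrt(mean(x[1, 200:1800]^2))
  expect_lt(20 * log10(gain), -25)
  ## 0.25 x Nyquist sinusoid: within +/- 1 dB
  xp <- matrix(sin(pi * 0.25 * t), 1)
  yp <- lowpass_filter(xp, b)
  gp <- sqrt(mean(yp[1, 200:1800]^2)) / sqrt(mean(xp[1, 200:1800]^2))
  expect_lt(abs(20 * log10(gp)), 1)
})

test_that("flat and single-transient traces detect as expected", {
  expect_equal(sum(detect_events(matrix(0, 2, 500))$values), 0)
  tr <- kernel_trace(101, 500, amp = 0.3)
  det <- detect_events(matrix(tr, 1), event_params(0.1, 0.1, 0.3),
                       prefilter = TRUE)
  expect_equal(det$onsets[[1]], 101)
  ## extent mode marks the supra-baseline run, onset mode a single frame
  expect_gt(sum(det$values), 1)
  det1 <- detect_events(matrix(tr, 1), event_params(0.1, 0.1, 0.3),
                        prefilter = TRUE, mode = "onset")
  expect_equal(sum(det1$values), 1)
  expect_error(detect_events(matrix(NA_real_, 1, 100)), "all-NaN")
})

test_that("detection is translation-equivariant away from edges", {
  onsets <- c(120, 260, 401)
  tr1 <- kernel_trace(onsets, 800)
  tr2 <- kernel_trace(onsets + 37, 800)
  p <- event_params(0.1, 0.1, 0.3)
  d1 <- detect_events(matrix(tr1, 1), p)$onsets[[1]]
  d2 <- detect_events(matrix(tr2, 1), p)$onsets[[1]]
  expect_equal(d2, d1 + 37)
})

test_that("raising any threshold never increases the event count", {
  set.seed(42)
  spec <- session_spec(n_neurons = 4, baseline_rate = 0.004,
                       epoch_plan = social_epoch_plan(pre_frames = 400,
                                                      interaction_frames = 400)[1])
  s <- generate_session(spec, truth_config(social_frac = 0), seed = 6)
  filt <- lowpass_filter(s$traces)
  n_events <- function(p) sum(lengths(detect_events(filt, p,
                                                    prefilter = FALSE)$onsets))
  base <- event_params(0.05, 0.1, 0.2)
  n0 <- n_events(base)
  expect_lte(n_events(event_params(0.08, 0.1, 0.2)), n0)
  expect_lte(n_events(event_params(0.05, 0.2, 0.2)), n0)
  expect_lte(n_events(event_params(0.05, 0.1, 0.6)), n0)
})

test_that("tuning selects the exhaustive-search optimum and reaches 95/95", {
  spec <- session_spec(n_neurons = 10, baseline_rate = 0.004,
                       epoch_plan = social_epoch_plan(pre_frames = 1500,
                                                      interaction_frames = 1500)[1:2])
  s <- generate_session(spec, truth_config(social_frac = 0), seed = 5)
  grid <- expand.grid(derivative_min = c(0.04, 0.08, 0.3),
                      amplitude_min = c(0.05, 0.15, 0.4),
                      auc_min = c(0.1, 0.5, 2))
  tuned <- tune_detector(s$traces, s$raster, grid)
  sc <- attr(tuned, "scores")
  expect_gte(sc$sensitivity, 0.95)
  expect_gte(sc$specificity, 0.95)
  ## independent exhaustive re-scoring of every grid point
  filt <- lowpass_filter(s$traces)
  crit <- vapply(seq_len(nrow(grid)), function(k) {
    det <- detect_events(filt, event_params(grid$derivative_min[k],
                                            grid$amplitude_min[k],
                                            grid$auc_min[k]),
                         prefilter = FALSE)
    sc <- detection_scores(det, s$raster)
    min(sc$sensitivity, sc$specificity)
  }, numeric(1))
  expect_equal(unlist(tuned, use.names = FALSE),
               unlist(grid[which.max(crit), ], use.names = FALSE))
  expect_error(tune_detector(s$traces, s$raster, grid[0, ]), "empty")
})

test_that("zero-event truth reports undefined sensitivity", {
  tr <- matrix(0, 2, 300)
  det <- detect_events(tr)
  sc <- detection_scores(det, matrix(0L, 2, 300))
  expect_true(is.na(sc$sensitivity))
  expect_equal(sc$specificity, 1)
})

test_that("z-scoring normalizes, is idempotent, and flags constant traces", {
  expect_equal(as.numeric(zscore_traces(matrix(c(0, 2), 1))), c(-1, 1))
  set.seed(1)
  x <- matrix(rnorm(5 * 400, mean = 3, sd = 2), 5)
  z <- zscore_traces(x)
  expect_equal(rowMeans(z), rep(0, 5))
  expect_equal(sqrt(rowMeans(z^2)), rep(1, 5))
  expect_equal(unclass(zscore_traces(z)), unclass(z), ignore_attr = TRUE)
  zc <- zscore_traces(rbind(x[1, ], 7))
  expect_equal(attr(zc, "excluded"), 2L)
})
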