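test_that("exhaustive circular null matches hand enumeration", {
  ## 12-frame row with events at frames 0,1; statistic mask frames 0-3.
  ## Enumerating all 12 shifts by hand gives mean-in-mask values
  ## {0.5 x3, 0.25 x2, 0 x7}; observed 0.5 -> mid-rank (9 + 1.5)/12.
  row <- c(1, 1, rep(0, 10))
  nd <- circular_null(row, mask = 1:4, exhaustive = TRUE)
  expect_equal(sort(nd$values),
               sort(c(rep(0.5, 3), rep(0.25, 2), rep(0, 7))))
  expect_equal(nd$observed, 0.5)
  expect_equal(modulation_index(nd), 87.5)
})

test_that("sampled null agrees with direct-shift recomputation", {
  set.seed(11)
  x <- rbinom(50, 1, 0.3)
  m <- sort(sample(50, 17))
  nd <- circular_null(x, m, exhaustive = TRUE)
  direct <- vapply(0:49, function(s)
    mean(x[((seq_along(x) - 1 - s) %% 50) + 1][m]), numeric(1))
  expect_equal(nd$values, direct)
  ## difference statistic
  m2 <- setdiff(1:50, m)[1:20]
  nd2 <- circular_null(x, m, m2, exhaustive = TRUE)
  d2 <- vapply(0:49, function(s) {
    xs <- x[((seq_along(x) - 1 - s) %% 50) + 1]
    mean(xs[m]) - mean(xs[m2])
  }, numeric(1))
  expect_equal(nd2$values, d2)
  ## sampled mode draws from the same enumerated support
  set.seed(2)
  nds <- circular_null(x, m, n_shuffles = 500)
  expect_true(all(nds$values %in% nd$values))
  expect_length(nds$values, 500)
})

test_that("degenerate and extreme nulls land at the mid-rank bounds", {
  ## neuron active every frame: null degenerate at the observed value
  nd <- circular_null(rep(1, 20), 1:5, exhaustive = TRUE)
  expect_equal(modulation_index(nd), 50)
  ## observed above every other shift: rank extremum 100 x (1 - 0.5/n)
  spike <- c(1, rep(0, 399))
  expect_equal(modulation_index(circular_null(spike, 1, exhaustive = TRUE)),
               100 * (1 - 0.5 / 400))
  set.seed(1)
  expect_equal(modulation_index(circular_null(spike, 1, n_shuffles = 100)),
               100 * (1 - 0.5 / 100))
  expect_true(is.na(modulation_index(NaN, rep(0, 10))))
  expect_error(circular_null(c(1), 1), "at least 2")
})

test_that("context split antisymmetry: swapped split maps index to 100 - index", {
  s <- tiny_social_session(seed = 23, n_neurons = 20,
                           pre_frames = 400, interaction_frames = 400)
  ab <- context_modulation(s$raster, s$annotation,
                           split = list(AB = c("A", "B"), CD = c("C", "D")),
                           exhaustive = TRUE)
  ba <- context_modulation(s$raster, s$annotation,
                           split = list(CD = c("C", "D"), AB = c("A", "B")),
                           exhaustive = TRUE)
  ok <- !ab$excluded
  expect_equal(ab$index[ok] + ba$index[ok], rep(100, sum(ok)))
})

test_that("planted social gains drive indices into the expected tails", {
  s <- tiny_social_session(seed = 29, n_neurons = 60, dynamic = FALSE,
                           pre_frames = 1500, interaction_frames = 1500,
                           truth = truth_config(social_frac = 0.3,
                                                social_gains = c(3, 1/3),
                                                context_frac = 0))
  mv <- behavior_modulation(s$raster, s$annotation, c("A", "B"),
                            contrast = "difference",
                            n_shuffles = 1000, seed = 1)
  up <- s$truth$social_dir > 0
  dn <- s$truth$social_dir < 0
  expect_true(all(mv$index[up] > 90, na.rm = TRUE))
  expect_true(all(mv$index[dn] < 10, na.rm = TRUE))
})

test_that("without planted effects indices are uniform on (0, 100)", {
  s <- null_session(seed = 41)
  mv <- behavior_modulation(s$raster, s$annotation, "A",
                            exhaustive = TRUE)
  idx <- mv$index[!mv$excluded]
  ks <- suppressWarnings(stats::ks.test(idx / 100, "punif"))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(length(idx)))
  expect_lt(abs(mean(idx > 90) - 0.1), 0.12)
})

test_that("maze and arm modulation recover the planted open-arm ensemble", {
  spec <- session_spec(n_neurons = 60,
                       epoch_plan = maze_epoch_plan(hc_frames = 1500,
                                                    maze_frames = 3000))
  s <- generate_maze_session(spec,
                             truth_config(open_arm_frac = 0.25,
                                          open_arm_gains = c(3, 1/3),
                                          maze_frac = 0),
                             seed = 47)
  ezm <- arm_modulation(s$raster, s$annotation, "EZM",
                        maze_arms("EZM")[1:2], n_shuffles = 500, seed = 2)
  epm <- arm_modulation(s$raster, s$annotation, "EPM",
                        maze_arms("EPM")[1:2], n_shuffles = 500, seed = 3)
  planted <- s$truth$open_arm_gain != 1
  expect_gt(auc_score(abs(ezm$index - 50), planted), 0.9)
  ## shared plant: EZM and EPM open-arm vectors correlate positively
  ok <- !ezm$excluded & !epm$excluded
  expect_gt(cor(ezm$index[ok], epm$index[ok]), 0.3)
  expect_error(arm_modulation(s$raster, s$annotation, "EZM", "EPM_open1"),
               "never visited")
})

test_that("neurons inactive in both statistic masks are excluded", {
  s <- tiny_social_session(seed = 51, n_neurons = 10,
                           pre_frames = 200, interaction_frames = 200)
  raster <- s$raster
  raster[3, epoch_mask(s$annotation, c("A", "B"))] <- 0L
  mv <- behavior_modulation(raster, s$annotation, c("A", "B"),
                            n_shuffles = 100, seed = 1)
  expect_true(mv$excluded[3])
  expect_true(is.na(mv$index[3]))
})
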