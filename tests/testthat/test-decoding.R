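test_that("surrogate shuffles preserve margins and reach both tiny-matrix states", {
  set.seed(5)
  for (k in 1:20) {
    m <- matrix(rbinom(30 * 200, 1, 0.1), 30, 200)
    s <- surrogate_shuffle(m, seed = k)
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
  }
  ## all-ones matrix is the unique member of its margin class
  ones <- matrix(1L, 4, 5)
  expect_identical(surrogate_shuffle(ones, seed = 1), ones)
  ## 2x2 identity has exactly two margin-preserving configurations;
  ## across seeds both occur
  id2 <- diag(1L, 2)
  states <- vapply(1:40, function(k) surrogate_shuffle(id2, seed = k)[1, 1],
                   integer(1))
  expect_setequal(unique(states), c(0L, 1L))
})

test_that("classification metrics evaluate their defining ratios exactly", {
  m <- classification_metrics(tp = 1, fp = 1, fn = 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.25)
  expect_equal(m$f1, 1 / 3)
  expect_equal(classification_metrics(5, 0, 0)$f1, 1)
  m0 <- classification_metrics(tp = 0, fp = 0, fn = 4)
  expect_true(is.na(m0$precision))
  expect_equal(m0$recall, 0)
  ## F1 lies between precision and recall for random counts
  set.seed(9)
  for (k in 1:50) {
    cf <- rpois(3, 5) + c(1, 0, 0)
    m <- classification_metrics(cf[1], cf[2], cf[3])
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("a perfectly informative neuron yields near-perfect decoding", {
  n_frames <- 400
  soc <- rep(c(TRUE, FALSE), each = n_frames / 2)
  raster <- matrix(0L, 10, n_frames)
  raster[1, soc] <- 1L
  task <- decode_task(soc, !soc, n_iterations = 5, seed = 3)
  r <- train_eval(raster, task)
  expect_gt(mean(r$accuracy), 0.99)
})

test_that("decoder accuracy approaches the Bayes rate of the generative model", {
  ## closed-form generative model: 30 neurons, 10 informative with
  ## social rate 0.08 vs 0.02. The oracle classifies fresh frames by
  ## the exact log-likelihood ratio computed from the true rates.
  set.seed(77)
  n <- 30; n_frames <- 6000
  p_soc <- rep(0.02, n); p_soc[1:10] <- 0.08
  p_non <- rep(0.02, n)
  soc <- rep(c(TRUE, FALSE), each = n_frames / 2)
  raster <- matrix(0L, n, n_frames)
  for (i in 1:n)
    raster[i, ] <- rbinom(n_frames, 1, ifelse(soc, p_soc[i], p_non[i]))
  llr <- log(p_soc / p_non) - log((1 - p_soc) / (1 - p_non))
  bias <- sum(log((1 - p_soc) / (1 - p_non)))
  sim <- function(p) matrix(rbinom(n * 20000, 1, rep(p, 20000)), n)
  bayes <- (mean(colSums(sim(p_soc) * llr) + bias > 0) +
            mean(colSums(sim(p_non) * llr) + bias <= 0)) / 2
  task <- decode_task(soc, !soc, n_iterations = 30, max_per_class = 1000,
                      seed = 5)
  r <- train_eval(raster, task)
  expect_lt(abs(mean(r$accuracy) - bayes), 0.03)
})

test_that("decoder weights correlate with modulation indices on planted data", {
  s <- tiny_social_session(seed = 61, n_neurons = 60, dynamic = FALSE,
                           pre_frames = 1200, interaction_frames = 1200,
                           truth = truth_config(social_frac = 0.3,
                                                social_gains = c(3, 1/3),
                                                context_frac = 0))
  ann <- s$annotation
  task <- decode_task(social_mask(ann), nonsocial_mask(ann),
                      n_iterations = 20, max_per_class = 500, seed = 7)
  r <- train_eval(s$raster, task)
  mv <- behavior_modulation(s$raster, ann, c("A", "B", "C", "D"),
                            contrast = "difference", n_shuffles = 500,
                            seed = 8)
  expect_gt(weight_modulation_correlation(r, mv), 0.5)
  ## identical vectors correlate at exactly 1
  fake <- structure(list(beta = mv$index), class = "decode_result")
  expect_equal(weight_modulation_correlation(fake, mv), 1)
})

test_that("transfer evaluation enforces scope disjointness and balance", {
  s <- tiny_social_session(seed = 67, n_neurons = 30,
                           pre_frames = 400, interaction_frames = 400)
  ann <- s$annotation
  expect_error(transfer_eval(s$raster,
                             list(social_mask(ann, "A"), nonsocial_mask(ann, "A")),
                             list(A = list(social_mask(ann, "A"),
                                           nonsocial_mask(ann, "A")))),
               "overlaps")
  out <- transfer_eval(s$raster,
                       list(social_mask(ann, "A"), nonsocial_mask(ann, "A")),
                       list(B = list(social_mask(ann, "B"),
                                     nonsocial_mask(ann, "B"))),
                       n_iterations = 5, seed = 2)
  expect_equal(out$test, "B")
  expect_true(out$mean_acc >= 0 && out$mean_acc <= 1)
})

test_that("cross-context transfer distinguishes invariant from remapped plants", {
  run_transfer <- function(remap, seed) {
    s <- tiny_social_session(seed = seed, n_neurons = 60,
                             pre_frames = 1200, interaction_frames = 1200,
                             truth = truth_config(social_frac = 0.3,
                                                  social_gains = c(3, 1/3),
                                                  remap = remap))
    ann <- s$annotation
    transfer_eval(s$raster,
                  list(social_mask(ann, "A"), nonsocial_mask(ann, "A")),
                  list(B = list(social_mask(ann, "B"), nonsocial_mask(ann, "B")),
                       C = list(social_mask(ann, "C"), nonsocial_mask(ann, "C"))),
                  n_iterations = 20, max_per_class = 500, seed = 3)
  }
  off <- run_transfer(FALSE, 71)
  expect_gt(off$mean_acc[off$test == "C"], 0.55)   # cross-context transfers
  on <- run_transfer(TRUE, 72)
  expect_gt(on$mean_acc[on$test == "B"], 0.55)     # within-context still decodes
  expect_lt(abs(on$mean_acc[on$test == "C"] - 0.5), 0.05)  # remap: chance
})
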