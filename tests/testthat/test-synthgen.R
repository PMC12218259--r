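test_that("identical seeds give bit-identical sessions, different seeds differ", {
  a <- tiny_social_session(seed = 7, n_neurons = 15,
                           pre_frames = 300, interaction_frames = 300)
  b <- tiny_social_session(seed = 7, n_neurons = 15,
                           pre_frames = 300, interaction_frames = 300)
  c <- tiny_social_session(seed = 8, n_neurons = 15,
                           pre_frames = 300, interaction_frames = 300)
  expect_identical(a$raster, b$raster)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth$social_gain, b$truth$social_gain)
  expect_false(identical(a$raster, c$raster))
})

test_that("planted gains shift event rates as the binomial model predicts", {
  ## all neurons carry social gain 2 on baseline 0.02: social-frame rate
  ## 0.04; nonsocial-frame rate 0.02 (closed-form binomial oracle)
  s <- tiny_social_session(seed = 3, n_neurons = 30, dynamic = FALSE,
                           truth = truth_config(social_frac = 1,
                                                social_gains = 2,
                                                context_frac = 0))
  soc <- s$annotation$behavior == "social"
  n_soc <- sum(soc) * nrow(s$raster)
  n_non <- sum(!soc) * nrow(s$raster)
  p_soc <- mean(s$raster[, soc])
  p_non <- mean(s$raster[, !soc])
  expect_lt(abs(p_soc - 0.04), 4 * sqrt(0.04 * 0.96 / n_soc))
  expect_lt(abs(p_non - 0.02), 4 * sqrt(0.02 * 0.98 / n_non))

  ## no planted effect: social and nonsocial rates agree within 4 sigma
  s0 <- tiny_social_session(seed = 4, n_neurons = 30,
                            truth = truth_config(social_frac = 0,
                                                 context_frac = 0))
  soc0 <- s0$annotation$behavior == "social"
  d <- mean(s0$raster[, soc0]) - mean(s0$raster[, !soc0])
  se <- sqrt(0.02 * 0.98 * (1 / (sum(soc0) * 30) + 1 / (sum(!soc0) * 30)))
  expect_lt(abs(d), 4 * se)
})

test_that("every frame carries exactly one epoch, context, and behavior label", {
  s <- tiny_social_session(seed = 5, n_neurons = 5,
                           pre_frames = 400, interaction_frames = 400)
  ann <- s$annotation
  expect_equal(nrow(ann), ncol(s$raster))
  expect_false(any(is.na(ann$epoch_id)))
  expect_false(any(is.na(ann$behavior)))
  expect_true(all(ann$behavior %in% c("alone", "social", "present")))
  ## social frames only inside interaction windows (after the pre period)
  for (ep in unique(ann$epoch_id)) {
    sub <- ann[ann$epoch_id == ep, ]
    expect_true(all(sub$behavior[seq_len(400)] == "alone"))
  }
  ## epochs contiguous
  expect_equal(length(rle(ann$epoch_id)$values),
               length(unique(ann$epoch_id)))
})

test_that("invalid epoch and bout plans are rejected", {
  bad <- social_epoch_plan(pre_frames = 100, interaction_frames = 100)
  bad[[1]]$bout_plan <- list(list(start = 50, end = 150))   # starts in pre period
  expect_error(session_spec(epoch_plan = bad), "outside the interaction window")
  bad2 <- social_epoch_plan(pre_frames = 100, interaction_frames = 100)
  bad2[[2]]$bout_plan <- list(list(start = 100, end = 150),
                              list(start = 140, end = 180))
  expect_error(session_spec(epoch_plan = bad2), "overlapping")
  bad3 <- social_epoch_plan()
  bad3[[1]]$bout_plan <- list()
  expect_error(session_spec(epoch_plan = bad3), "empty bout_plan")
  expect_error(session_spec(baseline_rate = 1.2))
})

test_that("rates exceeding the clip bound warn and are clipped", {
  spec <- tiny_social_spec(n_neurons = 10, pre_frames = 100,
                           interaction_frames = 100, baseline_rate = 0.6)
  expect_warning(
    generate_session(spec, truth_config(social_frac = 1, social_gains = 3,
                                        context_frac = 0),
                     seed = 1, make_traces = FALSE),
    "clipped")
})

test_that("sessions round-trip losslessly through write/read", {
  s <- tiny_social_session(seed = 9, n_neurons = 8,
                           pre_frames = 150, interaction_frames = 150)
  d <- withr::local_tempdir()
  write_session(s, d)
  r <- read_session(d)
  expect_identical(r$raster, s$raster)
  expect_equal(r$annotation, s$annotation)
  expect_equal(r$truth$social_gain, s$truth$social_gain)
  expect_equal(r$truth$context_gain, s$truth$context_gain)
})

test_that("malformed session files raise parse errors naming the defect", {
  s <- tiny_social_session(seed = 9, n_neurons = 4,
                           pre_frames = 100, interaction_frames = 100)
  d <- withr::local_tempdir()
  write_session(s, d)
  ## non-binary raster entry
  rl <- readLines(file.path(d, "raster.tsv"))
  rl[2] <- sub("^0", "2", rl[2])
  writeLines(rl, file.path(d, "raster.tsv"))
  expect_error(read_session(d), "non-binary entry")
  ## annotation shorter than the raster
  write_session(s, d)
  al <- readLines(file.path(d, "annotation.tsv"))
  writeLines(al[1:100], file.path(d, "annotation.tsv"))
  expect_error(read_session(d), "frames but raster")
})

test_that("maze arm occupancy approaches the chain's stationary distribution", {
  ## symmetric transitions: doubly stochastic chain, uniform stationary law
  spec <- session_spec(n_neurons = 3,
                       epoch_plan = maze_epoch_plan(hc_frames = 200,
                                                    maze_frames = 30000,
                                                    mazes = "EZM"))
  s <- generate_maze_session(spec, truth_config(), seed = 12)
  occ <- table(s$annotation$arm[s$annotation$epoch_id == "EZM"])
  k <- length(maze_arms("EZM"))
  expect_setequal(names(occ), maze_arms("EZM"))
  expect_true(all(abs(occ / sum(occ) - 1 / k) < 0.05))
})

test_that("maze sessions carry arm labels only in maze epochs", {
  spec <- session_spec(n_neurons = 5,
                       epoch_plan = maze_epoch_plan(hc_frames = 300,
                                                    maze_frames = 300))
  s <- generate_maze_session(spec, truth_config(), seed = 2)
  ann <- s$annotation
  expect_true(all(is.na(ann$arm[grepl("^HC", ann$epoch_id)])))
  expect_false(any(is.na(ann$arm[ann$epoch_id %in% c("EZM", "EPM", "TM")])))
  expect_true(all(ann$arm[ann$epoch_id == "TM"] %in% maze_arms("TM")))
})
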