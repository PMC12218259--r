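#' Specify a synthetic imaging session
#'
#' A session specification bundles the acquisition geometry (number of
#' neurons, frame rate), the epoch layout, and the parameters of the
#' generative model for calcium activity: a per-frame Bernoulli event
#' probability per neuron, plus the kinetics used to render dF/F traces
#' from events (instant-rise, single-exponential-decay transients on top
#' of white noise).
#'
#' @param n_neurons number of neurons imaged. Default 80, matching the
#'   typical yield of a microendoscopic field of view.
#' @param frame_rate acquisition rate in Hz; one frame = 1/frame_rate s.
#' @param epoch_plan ordered list of epochs as produced by
#'   [social_epoch_plan()] or [maze_epoch_plan()].
#' @param baseline_rate per-frame probability that a neuron emits an
#'   event under no modulation; must lie strictly in (0, 1).
#' @param noise_sd standard deviation of the additive white noise on the
#'   rendered dF/F traces (dF/F units).
#' @param transient_tau decay time constant of a calcium transient, in
#'   seconds.
#' @param transient_amp_range two-element range; each transient's peak
#'   amplitude is drawn uniformly from this range, in multiples of
#'   `noise_sd`.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(n_neurons = 80L,
                         frame_rate = 20,
                         epoch_plan = social_epoch_plan(),
                         baseline_rate = 0.02,
                         noise_sd = 0.05,
                         transient_tau = 0.5,
                         transient_amp_range = c(4, 8)) {
  stopifnot(length(n_neurons) == 1L, n_neurons >= 1,
            frame_rate > 0,
            baseline_rate > 0, baseline_rate < 1,
            noise_sd > 0, transient_tau > 0,
            length(transient_amp_range) == 2L,
            transient_amp_range[1] > 0,
            transient_amp_range[2] >= transient_amp_range[1])
  if (length(epoch_plan) == 0L) stop("epoch_plan must contain at least one epoch")
  lapply(epoch_plan, validate_epoch)
  structure(list(n_neurons = as.integer(n_neurons),
                 frame_rate = frame_rate,
                 epoch_plan = epoch_plan,
                 baseline_rate = baseline_rate,
                 noise_sd = noise_sd,
                 transient_tau = transient_tau,
                 transient_amp_range = transient_amp_range),
            class = "session_spec")
}

validate_epoch <- function(ep) {
  need <- c("epoch_id", "context_id", "pre_frames", "interaction_frames")
  if (!all(need %in% names(ep)))
    stop("epoch entry missing fields: ",
         paste(setdiff(need, names(ep)), collapse = ", "))
  if (ep$pre_frames < 0 || ep$interaction_frames < 0 ||
      ep$pre_frames + ep$interaction_frames <= 0)
    stop("epoch ", ep$epoch_id, ": durations must be positive")
  if (!is.null(ep$bout_plan)) {
    bp <- ep$bout_plan
    if (length(bp) == 0L)
      stop("epoch ", ep$epoch_id, ": empty bout_plan (use NULL for automatic bouts)")
    lo <- ep$pre_frames
    hi <- ep$pre_frames + ep$interaction_frames
    prev_end <- -1L
    for (b in bp) {
      if (b$start < lo || b$end > hi || b$start >= b$end)
        stop("epoch ", ep$epoch_id, ": bout [", b$start, ", ", b$end,
             ") outside the interaction window [", lo, ", ", hi, ")")
      if (b$start < prev_end)
        stop("epoch ", ep$epoch_id, ": overlapping bouts")
      prev_end <- b$end
    }
  }
  invisible(ep)
}

#' Epoch layouts for the social-interaction experiment
#'
#' Four sequential epochs A-D. Each epoch starts with a pre-introduction
#' period during which the animal is alone (default 6000 frames = 5 min
#' at 20 Hz), followed by an interaction window of the same length during
#' which a novel conspecific is present and social bouts occur
#' intermittently. In the static layout all epochs share one context; in
#' the dynamic layout epochs A and B occur in context 1 and C and D in
#' context 2.
#'
#' @param dynamic if `TRUE`, epochs C and D are assigned a second context.
#' @param pre_frames frames of the alone period preceding each
#'   introduction.
#' @param interaction_frames frames of the conspecific-present window.
#' @param bout_plan optional explicit bout plan (list of
#'   `list(start =, end =)` with 0-based half-open frame intervals
#'   relative to the epoch start) applied to every epoch; `NULL` draws
#'   bouts at generation time.
#' @return list of epoch entries usable as `epoch_plan`.
#' @export
social_epoch_plan <- function(dynamic = FALSE,
                              pre_frames = 6000L,
                              interaction_frames = 6000L,
                              bout_plan = NULL) {
  ids <- c("A", "B", "C", "D")
  ctx <- if (dynamic) c("ctx1", "ctx1", "ctx2", "ctx2")
         else rep("ctx1", 4L)
  mapply(function(id, cx) {
    list(epoch_id = id, context_id = cx,
         pre_frames = as.integer(pre_frames),
         interaction_frames = as.integer(interaction_frames),
         bout_plan = bout_plan)
  }, ids, ctx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Epoch layout for the anxiety/maze experiment
#'
#' Home-cage blocks alternate with maze blocks: HC, maze, HC, maze, ...
#' so that every maze is preceded and followed by a home-cage epoch
#' (default 12000 frames = 10 min each at 20 Hz). Maze blocks carry an
#' arm-occupancy plan realized at generation time by a first-order Markov
#' chain over the maze's arm labels.
#'
#' @param mazes character vector of maze types among `"EZM"`, `"EPM"`,
#'   `"TM"`.
#' @param hc_frames frames per home-cage block.
#' @param maze_frames frames per maze block.
#' @param dwell_mean mean arm dwell time in frames (geometric dwell).
#' @return list of epoch entries usable as `epoch_plan`.
#' @export
maze_epoch_plan <- function(mazes = c("EZM", "EPM", "TM"),
                            hc_frames = 12000L,
                            maze_frames = 12000L,
                            dwell_mean = 100) {
  mazes <- match.arg(mazes, c("EZM", "EPM", "TM"), several.ok = TRUE)
  plan <- list()
  hc_i <- 1L
  add_hc <- function() {
    ep <- list(epoch_id = paste0("HC", hc_i), context_id = "HC",
               pre_frames = as.integer(hc_frames), interaction_frames = 0L,
               bout_plan = NULL)
    hc_i <<- hc_i + 1L
    ep
  }
  plan[[length(plan) + 1L]] <- add_hc()
  for (m in mazes) {
    plan[[length(plan) + 1L]] <-
      list(epoch_id = m, context_id = m,
           pre_frames = 0L, interaction_frames = as.integer(maze_frames),
           bout_plan = NULL, maze = m, dwell_mean = dwell_mean)
    plan[[length(plan) + 1L]] <- add_hc()
  }
  plan
}

#' Arm labels for each maze type
#'
#' EZM arms distinguish open vs closed and, for the closed arms, the
#' direction of travel (clockwise vs counter-clockwise); the EPM has two
#' open and two closed arms; the T-maze has one long and two short closed
#' arms.
#'
#' @param maze one of `"EZM"`, `"EPM"`, `"TM"`.
#' @return character vector of arm labels.
#' @export
maze_arms <- function(maze) {
  switch(match.arg(maze, c("EZM", "EPM", "TM")),
         EZM = c("EZM_open1", "EZM_open2", "EZM_closed_CW", "EZM_closed_CCW"),
         EPM = c("EPM_open1", "EPM_open2", "EPM_closed1", "EPM_closed2"),
         TM  = c("TM_long", "TM_short1", "TM_short2"))
}

is_open_arm <- function(arm) grepl("_open", arm)

#' Configure planted ground-truth modulation
#'
#' Defines how per-neuron multiplicative rate gains are drawn. Gains
#' compose multiplicatively on the baseline event rate; a gain above 1
#' raises a neuron's event probability during the relevant frames, a
#' gain below 1 suppresses it.
#'
#' @param social_frac fraction of neurons carrying a social gain.
#' @param social_gains candidate gain values for modulated neurons
#'   (positive; values below 1 plant negatively modulated neurons).
#' @param context_frac fraction of neurons carrying a context gain
#'   (applied in every context other than the first).
#' @param context_gains candidate context gain values.
#' @param context_link `"independent"` draws the context-modulated set
#'   independently of the social set; `"shared_sign"` reuses the social
#'   set with matching gain direction, planting correlated (non-orthogonal)
#'   representations.
#' @param remap if `TRUE`, the social ensemble is redrawn independently
#'   in each context (remapping); if `FALSE` social gains are identical
#'   across contexts (context-invariant encoding).
#' @param drift_rate per-frame geometric ramp of the baseline rate
#'   (0 = no drift).
#' @param open_arm_frac,open_arm_gains analogous plant for open-arm
#'   frames, shared between EZM and EPM (maze sessions only).
#' @param maze_frac,maze_gains analogous plant distinguishing maze
#'   contexts from home cage; the same ensemble is reused for every maze
#'   (context generalization) unless `maze_shared = FALSE`.
#' @param maze_shared reuse one maze-vs-HC ensemble across mazes.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(social_frac = 0.2,
                         social_gains = c(2, 0.5),
                         context_frac = 0.3,
                         context_gains = c(1.6, 0.625),
                         context_link = c("independent", "shared_sign"),
                         remap = FALSE,
                         drift_rate = 0,
                         open_arm_frac = 0.2,
                         open_arm_gains = c(2, 0.5),
                         maze_frac = 0.3,
                         maze_gains = c(1.6, 0.625),
                         maze_shared = TRUE) {
  stopifnot(social_frac >= 0, social_frac <= 1,
            all(social_gains > 0), all(context_gains > 0),
            context_frac >= 0, context_frac <= 1,
            all(open_arm_gains > 0), all(maze_gains > 0))
  structure(list(social_frac = social_frac, social_gains = social_gains,
                 context_frac = context_frac, context_gains = context_gains,
                 context_link = match.arg(context_link),
                 remap = isTRUE(remap), drift_rate = drift_rate,
                 open_arm_frac = open_arm_frac,
                 open_arm_gains = open_arm_gains,
                 maze_frac = maze_frac, maze_gains = maze_gains,
                 maze_shared = isTRUE(maze_shared)),
            class = "truth_config")
}

## sample() treats a length-1 x as 1:x; gains are values, never ranges
sample_gains <- function(gains, n) {
  if (length(gains) == 1L) rep(gains, n) else sample(gains, n, replace = TRUE)
}

## Draw per-neuron realized gains. Returns matrices indexed neuron x context.
realize_truth <- function(cfg, n, contexts) {
  k <- length(contexts)
  draw_set <- function(frac, gains) {
    g <- rep(1, n)
    n_mod <- round(frac * n)
    if (n_mod > 0) {
      idx <- sample.int(n, n_mod)
      g[idx] <- sample_gains(gains, n_mod)
    }
    g
  }
  base_sg <- draw_set(cfg$social_frac, cfg$social_gains)
  social_gain <- matrix(base_sg, n, k)
  if (cfg$remap) {
    for (j in seq_len(k)[-1L])
      social_gain[, j] <- draw_set(cfg$social_frac, cfg$social_gains)
  }
  context_gain <- matrix(1, n, k)
  if (k > 1L) {
    if (cfg$context_link == "shared_sign") {
      ## socially activated neurons are suppressed in later contexts (and
      ## vice versa), so social and first-vs-later-context preferences
      ## share sign neuron by neuron
      cg <- rep(1, n)
      up <- base_sg > 1; dn <- base_sg < 1
      cg[up] <- min(cfg$context_gains)
      cg[dn] <- max(cfg$context_gains)
    } else {
      cg <- draw_set(cfg$context_frac, cfg$context_gains)
    }
    for (j in seq_len(k)[-1L]) context_gain[, j] <- cg
  }
  colnames(social_gain) <- colnames(context_gain) <- contexts
  list(social_gain = social_gain,
       context_gain = context_gain,
       social_mod = base_sg != 1,
       social_dir = sign(log(base_sg)),
       remap = cfg$remap,
       drift_rate = cfg$drift_rate,
       config = cfg)
}

## Draw social bouts inside [lo, hi): alternating gaps and bouts with
## uniform lengths, scaled down for short windows so that every
## interaction window contains at least one bout. Consumes RNG state.
auto_bouts <- function(lo, hi, bout_range = c(200, 600), gap_range = c(100, 400)) {
  w <- hi - lo
  scl <- min(1, w / (bout_range[1] + gap_range[2] + 1))
  bout_range <- pmax(2, round(bout_range * scl))
  gap_range <- pmax(1, round(gap_range * scl))
  bouts <- list()
  pos <- lo + round(stats::runif(1, gap_range[1], gap_range[2]))
  repeat {
    len <- round(stats::runif(1, bout_range[1], bout_range[2]))
    if (pos + len > hi) {
      if (hi - pos > bout_range[1]) {
        bouts[[length(bouts) + 1L]] <- list(start = pos, end = hi)
      }
      break
    }
    bouts[[length(bouts) + 1L]] <- list(start = pos, end = pos + len)
    pos <- pos + len + round(stats::runif(1, gap_range[1], gap_range[2]))
    if (pos >= hi) break
  }
  if (length(bouts) == 0L) {
    q <- max(1L, w %/% 4L)
    bouts <- list(list(start = lo + q, end = hi - q))
  }
  bouts
}

## Simulate a first-order Markov chain over arm labels. Stay probability
## 1 - 1/dwell_mean (geometric dwell), uniform among the other arms
## otherwise.
simulate_arm_chain <- function(arms, n_frames, dwell_mean) {
  k <- length(arms)
  stay <- 1 - 1 / dwell_mean
  state <- sample.int(k, 1L)
  out <- integer(n_frames)
  move <- stats::runif(n_frames) > stay
  for (t in seq_len(n_frames)) {
    if (move[t]) {
      nxt <- sample.int(k - 1L, 1L)
      state <- if (nxt >= state) nxt + 1L else nxt
    }
    out[t] <- state
  }
  arms[out]
}

## Build the per-frame annotation table from an epoch plan. Consumes RNG
## state when bout plans or arm chains are drawn automatically.
build_annotation <- function(epoch_plan) {
  parts <- lapply(epoch_plan, function(ep) {
    n_pre <- ep$pre_frames
    n_int <- ep$interaction_frames
    n_tot <- n_pre + n_int
    behavior <- rep(NA_character_, n_tot)
    arm <- rep(NA_character_, n_tot)
    if (!is.null(ep$maze)) {
      behavior[] <- "explore"
      arm <- simulate_arm_chain(maze_arms(ep$maze), n_tot, ep$dwell_mean)
    } else {
      if (n_pre > 0) behavior[seq_len(n_pre)] <- "alone"
      if (n_int > 0) {
        behavior[n_pre + seq_len(n_int)] <- "present"
        bp <- ep$bout_plan
        if (is.null(bp)) bp <- auto_bouts(n_pre, n_tot)
        for (b in bp) behavior[(b$start + 1L):b$end] <- "social"
      }
    }
    data.frame(epoch_id = ep$epoch_id, context_id = ep$context_id,
               behavior = behavior, arm = arm,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, parts)
  ann <- cbind(frame = seq_len(nrow(ann)) - 1L, ann)
  rownames(ann) <- NULL
  ann
}

## Render dF/F traces from an event raster: each event contributes an
## instant-rise transient with exponential decay and a uniform amplitude,
## plus white noise.
render_traces <- function(raster, spec) {
  n <- nrow(raster); n_frames <- ncol(raster)
  decay <- exp(-1 / (spec$transient_tau * spec$frame_rate))
  amp_lo <- spec$transient_amp_range[1] * spec$noise_sd
  amp_hi <- spec$transient_amp_range[2] * spec$noise_sd
  traces <- matrix(0, n, n_frames)
  for (i in seq_len(n)) {
    imp <- numeric(n_frames)
    ev <- which(raster[i, ] == 1L)
    if (length(ev) > 0)
      imp[ev] <- stats::runif(length(ev), amp_lo, amp_hi)
    y <- stats::filter(imp, decay, method = "recursive")
    traces[i, ] <- as.numeric(y) + stats::rnorm(n_frames, 0, spec$noise_sd)
  }
  traces
}

## Assemble the neuron x frame rate matrix from annotation and realized
## truth, clipping at 0.95 to avoid saturation.
build_rate_matrix <- function(spec, ann, tr) {
  n <- spec$n_neurons
  n_frames <- nrow(ann)
  contexts <- colnames(tr$context_gain)
  ctx_idx <- match(ann$context_id, contexts)
  soc <- ann$behavior %in% "social"
  base <- rep(spec$baseline_rate, n_frames)
  if (tr$drift_rate != 0)
    base <- base * (1 + tr$drift_rate)^(seq_len(n_frames) - 1)
  rate <- matrix(0, n, n_frames)
  open_arm <- !is.na(ann$arm) & is_open_arm(ann$arm)
  for (i in seq_len(n)) {
    r <- base * tr$context_gain[i, ctx_idx]
    if (any(soc)) r[soc] <- r[soc] * tr$social_gain[i, ctx_idx[soc]]
    if (!is.null(tr$open_arm_gain) && any(open_arm))
      r[open_arm] <- r[open_arm] * tr$open_arm_gain[i]
    rate[i, ] <- r
  }
  if (any(rate > 0.95)) {
    warning("event rate exceeded 0.95 after gains for ",
            sum(rowSums(rate > 0.95) > 0), " neuron(s); clipped")
    rate <- pmin(rate, 0.95)
  }
  rate
}

#' Generate a synthetic social-interaction session
#'
#' Draws a binary event raster (independent Bernoulli events per neuron
#' per frame, with rate = baseline x planted gains), renders dF/F traces
#' from the raster, and returns the frame-aligned annotation and the
#' realized ground truth. Identical seeds give bit-identical sessions.
#'
#' @param spec a [session_spec()].
#' @param truth a [truth_config()].
#' @param seed integer seed; set before any random draw.
#' @param make_traces render dF/F traces (set `FALSE` to save time for
#'   raster-only analyses).
#' @return an object of class `ca_session` with elements `raster`
#'   (neurons x frames 0/1 matrix), `traces` (same shape dF/F matrix or
#'   `NULL`), `annotation` (one row per frame), `truth` (realized gains),
#'   `spec`, and `seed`.
#' @export
generate_session <- function(spec = session_spec(),
                             truth = truth_config(),
                             seed = 1L,
                             make_traces = TRUE) {
  stopifnot(inherits(spec, "session_spec"), inherits(truth, "truth_config"))
  set.seed(seed)
  ann <- build_annotation(spec$epoch_plan)
  contexts <- unique(ann$context_id)
  tr <- realize_truth(truth, spec$n_neurons, contexts)
  rate <- build_rate_matrix(spec, ann, tr)
  raster <- matrix(stats::rbinom(length(rate), 1L, as.vector(rate)),
                   nrow(rate), ncol(rate))
  traces <- if (make_traces) render_traces(raster, spec) else NULL
  structure(list(raster = raster, traces = traces, annotation = ann,
                 truth = tr, spec = spec, seed = seed),
            class = "ca_session")
}

#' Generate a synthetic anxiety/maze session
#'
#' Home-cage blocks alternate with maze blocks; arm occupancy within each
#' maze follows a first-order Markov chain with geometric dwell times.
#' Planted gains distinguish mazes from home cage (context) and open arms
#' from closed arms (anxiety-related information shared between EZM and
#' EPM).
#'
#' @inheritParams generate_session
#' @export
generate_maze_session <- function(spec = session_spec(epoch_plan = maze_epoch_plan()),
                                  truth = truth_config(),
                                  seed = 1L,
                                  make_traces = FALSE) {
  stopifnot(inherits(spec, "session_spec"), inherits(truth, "truth_config"))
  mazes <- unlist(lapply(spec$epoch_plan, function(ep) ep$maze))
  if (length(mazes) == 0L)
    stop("epoch_plan contains no maze epochs; use maze_epoch_plan()")
  set.seed(seed)
  ann <- build_annotation(spec$epoch_plan)
  contexts <- unique(ann$context_id)   # "HC" plus one per maze
  n <- spec$n_neurons
  tr <- realize_truth(truth, n, contexts)
  ## maze-vs-HC plant: overwrite context gains (HC column = 1)
  draw <- function(frac, gains) {
    g <- rep(1, n)
    n_mod <- round(frac * n)
    if (n_mod > 0) {
      idx <- sample.int(n, n_mod)
      g[idx] <- sample_gains(gains, n_mod)
    }
    g
  }
  cg <- matrix(1, n, length(contexts), dimnames = list(NULL, contexts))
  shared <- draw(truth$maze_frac, truth$maze_gains)
  for (m in mazes) {
    cg[, m] <- if (truth$maze_shared) shared else draw(truth$maze_frac, truth$maze_gains)
  }
  tr$context_gain <- cg
  tr$open_arm_gain <- draw(truth$open_arm_frac, truth$open_arm_gains)
  rate <- build_rate_matrix(spec, ann, tr)
  raster <- matrix(stats::rbinom(length(rate), 1L, as.vector(rate)),
                   nrow(rate), ncol(rate))
  traces <- if (make_traces) render_traces(raster, spec) else NULL
  structure(list(raster = raster, traces = traces, annotation = ann,
                 truth = tr, spec = spec, seed = seed),
            class = "ca_session")
}

#' @export
print.ca_session <- function(x, ...) {
  cat("<ca_session> ", nrow(x$raster), " neurons x ", ncol(x$raster),
      " frames @ ", x$spec$frame_rate, " Hz\n", sep = "")
  cat("  epochs: ", paste(unique(x$annotation$epoch_id), collapse = ", "),
      "\n  contexts: ", paste(unique(x$annotation$context_id), collapse = ", "),
      "\n  traces: ", if (is.null(x$traces)) "absent" else "present",
      "\n  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a session to a directory of plain-text files
#'
#' Writes `raster.tsv` (neurons as rows, frames as columns, values 0/1),
#' optionally `traces.tsv` (same layout, dF/F), `annotation.tsv` (one row
#' per frame: frame, epoch_id, context_id, behavior, arm), and
#' `truth.yaml` (per-neuron realized gains). The round trip through
#' [read_session()] is lossless for raster, annotation, and truth.
#'
#' @param session a `ca_session`.
#' @param path directory to create/write into.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ca_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(session$raster, file.path(path, "raster.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(session$traces))
    utils::write.table(signif(session$traces, 7), file.path(path, "traces.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  ann <- session$annotation
  ann$arm[is.na(ann$arm)] <- ""
  utils::write.table(ann, file.path(path, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  tr <- session$truth
  yaml::write_yaml(
    list(contexts = colnames(tr$context_gain),
         frame_rate = session$spec$frame_rate,
         drift_rate = tr$drift_rate,
         remap = tr$remap,
         seed = session$seed,
         neurons = lapply(seq_len(nrow(tr$social_gain)), function(i) {
           rec <- list(neuron = i,
                       social_gain = as.numeric(tr$social_gain[i, ]),
                       context_gain = as.numeric(tr$context_gain[i, ]))
           if (!is.null(tr$open_arm_gain))
             rec$open_arm_gain <- tr$open_arm_gain[i]
           rec
         })),
    file.path(path, "truth.yaml"))
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' Validates that the raster is strictly binary and that the annotation
#' covers exactly the raster's frames; malformed files raise errors
#' naming the offending entry.
#'
#' @param path directory containing the session files.
#' @return a `ca_session` (with `truth` and `traces` present when their
#'   files exist).
#' @export
read_session <- function(path) {
  rf <- file.path(path, "raster.tsv")
  af <- file.path(path, "annotation.tsv")
  if (!file.exists(rf)) stop("missing raster file: ", rf)
  if (!file.exists(af)) stop("missing annotation file: ", af)
  raster <- as.matrix(utils::read.table(rf, sep = "\t", header = FALSE))
  dimnames(raster) <- NULL
  bad <- which(!(raster %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(raster)) + 1
    j <- ((bad[1] - 1) %/% nrow(raster)) + 1
    stop("raster.tsv: non-binary entry '", raster[bad[1]],
         "' at row ", i, ", column ", j)
  }
  storage.mode(raster) <- "integer"
  ann <- utils::read.table(af, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character", "character",
                                          "character", "character"))
  need <- c("frame", "epoch_id", "context_id", "behavior", "arm")
  if (!identical(names(ann), need))
    stop("annotation.tsv: expected columns ", paste(need, collapse = ", "),
         " but found ", paste(names(ann), collapse = ", "))
  if (nrow(ann) != ncol(raster))
    stop("annotation has ", nrow(ann), " frames but raster has ",
         ncol(raster), " columns")
  if (!identical(ann$frame, seq_len(nrow(ann)) - 1L))
    stop("annotation.tsv: frame column must be 0-based and consecutive")
  ann$arm[ann$arm == ""] <- NA_character_
  traces <- NULL
  tf <- file.path(path, "traces.tsv")
  if (file.exists(tf)) {
    traces <- as.matrix(utils::read.table(tf, sep = "\t", header = FALSE))
    dimnames(traces) <- NULL
    if (!all(dim(traces) == dim(raster)))
      stop("traces.tsv shape ", nrow(traces), "x", ncol(traces),
           " does not match raster ", nrow(raster), "x", ncol(raster))
  }
  truth <- NULL
  frame_rate <- 20
  yf <- file.path(path, "truth.yaml")
  if (file.exists(yf)) {
    y <- yaml::read_yaml(yf)
    contexts <- unlist(y$contexts)
    sg <- t(vapply(y$neurons, function(r) as.numeric(unlist(r$social_gain)),
                   numeric(length(contexts))))
    cg <- t(vapply(y$neurons, function(r) as.numeric(unlist(r$context_gain)),
                   numeric(length(contexts))))
    colnames(sg) <- colnames(cg) <- contexts
    truth <- list(social_gain = sg, context_gain = cg,
                  social_mod = sg[, 1] != 1,
                  social_dir = sign(log(sg[, 1])),
                  remap = isTRUE(y$remap), drift_rate = y$drift_rate)
    if (!is.null(y$neurons[[1]]$open_arm_gain))
      truth$open_arm_gain <- vapply(y$neurons, function(r) r$open_arm_gain,
                                    numeric(1))
    if (!is.null(y$frame_rate)) frame_rate <- y$frame_rate
  }
  spec <- list(n_neurons = nrow(raster), frame_rate = frame_rate)
  structure(list(raster = raster, traces = traces, annotation = ann,
                 truth = truth, spec = spec, seed = NA_integer_),
            class = "ca_session")
}
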