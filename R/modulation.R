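## Circular cross-correlation counts via FFT: for binary row x and mask
## indicator m (both length T), returns the integer vector
##   c[s] = sum_i m[i] * x[(i - s) mod T],  s = 0, ..., T-1,
## i.e. the number of events falling in the mask after circularly
## shifting the row forward by s frames. Exact because x and m are
## binary: the FFT result is rounded back to integers.
circshift_counts <- function(x, mask_idx) {
  T <- length(x)
  m <- numeric(T)
  m[mask_idx] <- 1
  cc <- Re(stats::fft(Conj(stats::fft(x)) * stats::fft(m), inverse = TRUE)) / T
  as.integer(round(cc))
}

#' Circular-shift null distribution for one neuron
#'
#' The null hypothesis preserves a neuron's autocorrelated event
#' structure while breaking its alignment to behavior: the neuron's
#' scope-restricted activity row is circularly shifted by a uniform
#' random offset and the statistic is recomputed. Offsets are drawn
#' uniformly from \{0, ..., T-1\} with replacement (`n_shuffles` draws,
#' of which the first is always the identity shift, so the null sample
#' contains the observed statistic), or enumerated exhaustively over
#' all T shifts.
#'
#' @param row binary activity of one neuron over the scope frames
#'   (already restricted and concatenated).
#' @param mask frames (indices into `row`, or logical) defining the
#'   condition whose mean activity is the statistic.
#' @param mask2 optional second frame set; when given the statistic is
#'   mean(mask) - mean(mask2).
#' @param n_shuffles number of sampled shifts (ignored when
#'   `exhaustive`).
#' @param exhaustive enumerate all T shifts instead of sampling.
#' @return list of class `circ_null` with `values` (null statistics),
#'   `observed` (statistic at shift 0), `n_shuffles`, and `kind`.
#' @note Consumes RNG state when sampling; seed at the caller.
#' @export
circular_null <- function(row, mask, mask2 = NULL,
                          n_shuffles = 10000L, exhaustive = FALSE) {
  T <- length(row)
  if (T < 2L) stop("scope length must be at least 2")
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L) stop("empty statistic mask")
  c1 <- circshift_counts(row, mask)
  stat <- c1 / length(mask)
  kind <- "mean_in_mask"
  if (!is.null(mask2)) {
    if (is.logical(mask2)) mask2 <- which(mask2)
    if (length(mask2) == 0L) stop("empty second mask")
    stat <- stat - circshift_counts(row, mask2) / length(mask2)
    kind <- "mean_difference"
  }
  observed <- stat[1L]
  if (exhaustive) {
    values <- stat
    n_shuffles <- T
  } else {
    ## the identity shift is always one of the draws (as in exhaustive
    ## mode), bounding indices away from 0 and 100 by 50/n_shuffles
    shifts <- c(1L, sample.int(T, n_shuffles - 1L, replace = TRUE))
    values <- stat[shifts]
  }
  structure(list(values = values, observed = observed,
                 n_shuffles = n_shuffles, kind = kind),
            class = "circ_null")
}

#' Percentile modulation index from a null distribution
#'
#' Mid-rank convention: ties between the observed statistic and null
#' values contribute half weight, so a neuron whose null is degenerate
#' at the observed value lands at 50 rather than 0 or 100.
#'
#' @param observed observed statistic (or a `circ_null`, in which case
#'   its own observed value is used).
#' @param null a `circ_null` or numeric vector of null statistics.
#' @return index in \[0, 100\]; `NA` for a non-finite observed statistic.
#' @export
modulation_index <- function(observed, null = NULL) {
  if (inherits(observed, "circ_null")) {
    null <- observed$values
    observed <- observed$observed
  } else if (inherits(null, "circ_null")) {
    null <- null$values
  }
  if (length(null) == 0L) stop("empty null distribution")
  if (!is.finite(observed)) return(NA_real_)
  eps <- 1e-9
  below <- sum(null < observed - eps)
  ties <- sum(abs(null - observed) <= eps)
  100 * (below + 0.5 * ties) / length(null)
}

## Shared driver: per-neuron circular null + index over a scope.
## statistic masks are given as indices into the scope frames.
mod_vector_core <- function(raster, scope_frames, mask, mask2,
                            n_shuffles, exhaustive, exclude) {
  n <- nrow(raster)
  idx <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (exclude[i]) next
    nd <- circular_null(raster[i, scope_frames], mask, mask2,
                        n_shuffles = n_shuffles, exhaustive = exhaustive)
    idx[i] <- modulation_index(nd)
  }
  idx
}

new_mod_vector <- function(index, excluded, scope, contrast, n_shuffles) {
  out <- data.frame(neuron = seq_along(index), index = index,
                    excluded = excluded)
  attr(out, "scope") <- scope
  attr(out, "contrast") <- contrast
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("mod_vector", class(out))
  out
}

#' Behavioral modulation indices
#'
#' For each neuron, the mean activity during the behavior's frames
#' within the scope (a set of epochs), expressed as a percentile of the
#' circular-shift null over the scope's concatenated frames. In
#' `contrast = "difference"` mode the statistic is instead the
#' difference between mean activity in the behavior frames and in the
#' nonsocial frames. Neurons with no events in either the behavior or
#' the nonsocial frames are excluded (no index).
#'
#' @param raster binary neurons x frames matrix.
#' @param annotation session annotation.
#' @param scope character vector of epoch ids; epochs are concatenated
#'   and a single circular shift spans the concatenation.
#' @param behavior behavior label (default `"social"`).
#' @param contrast `"mean"` (epoch-specific index: mean activity in the
#'   behavior mask) or `"difference"` (behavior minus nonsocial).
#' @param nonsocial nonsocial definition passed to [nonsocial_mask()].
#' @param n_shuffles shifts per neuron (default 10000).
#' @param seed integer seed (set once; per-neuron draws follow one
#'   stream).
#' @param exhaustive enumerate all shifts.
#' @return a `mod_vector` data frame: `neuron`, `index`, `excluded`.
#' @export
behavior_modulation <- function(raster, annotation, scope,
                                behavior = "social",
                                contrast = c("mean", "difference"),
                                nonsocial = "all",
                                n_shuffles = 10000L, seed = NULL,
                                exhaustive = FALSE) {
  contrast <- match.arg(contrast)
  if (!is.null(seed)) set.seed(seed)
  scope_frames <- which(epoch_mask(annotation, scope))
  if (length(scope_frames) == 0L)
    stop("scope epochs not found: ", paste(scope, collapse = ", "))
  beh_all <- annotation$behavior[scope_frames] %in% behavior
  if (!any(beh_all))
    stop("behavior '", behavior, "' absent in scope ",
         paste(scope, collapse = ","))
  non_all <- nonsocial_mask(annotation, definition = nonsocial)[scope_frames]
  sub <- raster[, scope_frames, drop = FALSE]
  excl <- rowSums(sub[, beh_all, drop = FALSE]) == 0 &
          rowSums(sub[, non_all, drop = FALSE]) == 0
  mask2 <- if (contrast == "difference") which(non_all) else NULL
  idx <- mod_vector_core(raster, scope_frames, which(beh_all), mask2,
                         n_shuffles, exhaustive, excl)
  new_mod_vector(idx, excl, paste(scope, collapse = ""),
                 paste0(behavior, if (contrast == "difference") "-vs-nonsocial"),
                 n_shuffles)
}

#' Context modulation indices
#'
#' Per neuron, the difference between mean activity over the first and
#' second epoch sets (all frames, social and nonsocial), expressed as a
#' percentile of the null distribution of such differences under
#' circular shifts of the concatenated scope. Neurons with no events in
#' either epoch set are excluded.
#'
#' @param raster binary neurons x frames matrix.
#' @param annotation session annotation.
#' @param split list of two character vectors of epoch ids (e.g.
#'   `list(AB = c("A","B"), CD = c("C","D"))`).
#' @inheritParams behavior_modulation
#' @return a `mod_vector`.
#' @export
context_modulation <- function(raster, annotation,
                               split = list(AB = c("A", "B"),
                                            CD = c("C", "D")),
                               n_shuffles = 10000L, seed = NULL,
                               exhaustive = FALSE) {
  stopifnot(length(split) == 2L)
  if (!is.null(seed)) set.seed(seed)
  all_ep <- c(split[[1]], split[[2]])
  scope_frames <- which(epoch_mask(annotation, all_ep))
  m1 <- annotation$epoch_id[scope_frames] %in% split[[1]]
  m2 <- annotation$epoch_id[scope_frames] %in% split[[2]]
  if (!any(m1) || !any(m2))
    stop("empty epoch set in context split")
  sub <- raster[, scope_frames, drop = FALSE]
  excl <- rowSums(sub[, m1, drop = FALSE]) == 0 &
          rowSums(sub[, m2, drop = FALSE]) == 0
  idx <- mod_vector_core(raster, scope_frames, which(m1), which(m2),
                         n_shuffles, exhaustive, excl)
  nm <- names(split)
  if (is.null(nm)) nm <- c("set1", "set2")
  new_mod_vector(idx, excl, paste(all_ep, collapse = ""),
                 paste0(nm[1], "-minus-", nm[2]), n_shuffles)
}

#' Region modulation indices (maze and arm modes)
#'
#' Generic mean-in-mask modulation over an arbitrary scope: the mean
#' activity of each neuron within the target frames, as a percentile of
#' the circular-shift null over the scope. Used for maze-vs-home-cage
#' ensembles (scope = maze plus adjacent home-cage epochs, target =
#' maze frames) and arm ensembles (scope = one maze, target = one arm's
#' frames).
#'
#' @param raster binary neurons x frames matrix.
#' @param scope_frames frame indices (1-based) defining the shuffle
#'   scope.
#' @param target_frames frame indices (subset of `scope_frames`) whose
#'   mean activity is the statistic.
#' @param label contrast label stored on the result.
#' @inheritParams behavior_modulation
#' @return a `mod_vector`.
#' @export
region_modulation <- function(raster, scope_frames, target_frames,
                              label = "region", n_shuffles = 10000L,
                              seed = NULL, exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(target_frames %in% scope_frames))
    stop("target frames must lie within the scope")
  mask <- match(target_frames, scope_frames)
  sub <- raster[, scope_frames, drop = FALSE]
  excl <- rowSums(sub) == 0
  idx <- mod_vector_core(raster, scope_frames, mask, NULL,
                         n_shuffles, exhaustive, excl)
  new_mod_vector(idx, excl, "custom", label, n_shuffles)
}

#' Maze-vs-home-cage modulation
#'
#' Mean activity of each neuron within a maze as a percentile relative
#' to circular shuffles across all frames from that maze and the
#' adjacent home-cage epochs.
#'
#' @param raster binary neurons x frames matrix.
#' @param annotation maze-session annotation.
#' @param maze maze epoch id (e.g. `"EZM"`).
#' @param hc_epochs ids of the adjacent home-cage epochs; by default the
#'   epochs immediately before and after the maze in the annotation.
#' @inheritParams behavior_modulation
#' @export
maze_modulation <- function(raster, annotation, maze, hc_epochs = NULL,
                            n_shuffles = 10000L, seed = NULL,
                            exhaustive = FALSE) {
  eps <- rle(annotation$epoch_id)$values
  pos <- match(maze, eps)
  if (is.na(pos)) stop("maze epoch '", maze, "' not found")
  if (is.null(hc_epochs))
    hc_epochs <- eps[c(pos - 1L, pos + 1L)[c(pos > 1L, pos < length(eps))]]
  scope <- which(annotation$epoch_id %in% c(maze, hc_epochs))
  target <- which(annotation$epoch_id == maze)
  region_modulation(raster, scope, target,
                    label = paste0(maze, "-vs-HC"),
                    n_shuffles = n_shuffles, seed = seed,
                    exhaustive = exhaustive)
}

#' Arm modulation within a maze
#'
#' Mean activity during occupancy of the given arm(s), as a percentile
#' relative to circular shuffles across all frames of that maze.
#'
#' @param raster binary neurons x frames matrix.
#' @param annotation maze-session annotation.
#' @param maze maze epoch id.
#' @param arms arm labels defining the target (e.g. both open arms).
#' @inheritParams behavior_modulation
#' @export
arm_modulation <- function(raster, annotation, maze, arms,
                           n_shuffles = 10000L, seed = NULL,
                           exhaustive = FALSE) {
  scope <- which(annotation$epoch_id == maze)
  if (length(scope) == 0L) stop("maze epoch '", maze, "' not found")
  in_arm <- arm_mask(annotation, arms)[scope]
  if (!any(in_arm))
    stop("arm(s) never visited in ", maze, ": ", paste(arms, collapse = ", "))
  region_modulation(raster, scope, scope[in_arm],
                    label = paste0(maze, ":", paste(arms, collapse = "+")),
                    n_shuffles = n_shuffles, seed = seed,
                    exhaustive = exhaustive)
}
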