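#' Design the equiripple low-pass filter used on dF/F traces
#'
#' Parks-McClellan (equiripple FIR) design with a passband edge at
#' `pass` and stopband edge at `stop`, both as fractions of the Nyquist
#' frequency. The order is increased from a Kaiser-style estimate until
#' the realized response meets the ripple and attenuation requirements;
#' failure to meet them within a generous order bound is a design error.
#'
#' @param pass passband edge, fraction of Nyquist (default 0.5).
#' @param stop stopband edge, fraction of Nyquist (default 0.65).
#' @param ripple_db maximum passband ripple in dB (default 1).
#' @param atten_db minimum stopband attenuation in dB (default 25).
#' @return numeric vector of filter coefficients with attributes
#'   `group_delay` (frames) and `spec`.
#' @export
design_lowpass <- function(pass = 0.5, stop = 0.65,
                           ripple_db = 1, atten_db = 25) {
  stopifnot(pass > 0, pass < stop, stop < 1, ripple_db > 0, atten_db > 0)
  dp <- (10^(ripple_db / 20) - 1) / (10^(ripple_db / 20) + 1)
  ds <- 10^(-atten_db / 20)
  df <- (stop - pass) / 2                     # cycles/sample
  n_est <- max(8L, ceiling((-20 * log10(sqrt(dp * ds)) - 13) / (14.6 * df)))
  n_est <- n_est + n_est %% 2L          # even order: integer group delay
  for (n in seq(n_est, n_est + 80L, by = 2L)) {
    b <- tryCatch(signal::remez(n, c(0, pass, stop, 1), c(1, 1, 0, 0)),
                  error = function(e) NULL)
    if (is.null(b)) next
    h <- filter_response(b, seq(0, 1, by = 0.001))
    pass_mag <- 20 * log10(abs(h[seq(0, 1, by = 0.001) <= pass]))
    stop_mag <- 20 * log10(pmax(abs(h[seq(0, 1, by = 0.001) >= stop]), 1e-12))
    if (max(abs(pass_mag)) <= ripple_db && max(stop_mag) <= -atten_db) {
      b <- as.numeric(b)
      attr(b, "group_delay") <- (length(b) - 1) / 2
      attr(b, "spec") <- list(pass = pass, stop = stop,
                              ripple_db = ripple_db, atten_db = atten_db)
      return(b)
    }
  }
  stop("could not meet filter specification (pass=", pass, ", stop=", stop,
       ", ripple=", ripple_db, " dB, attenuation=", atten_db, " dB)")
}

#' Frequency response of an FIR filter
#'
#' @param b FIR coefficients.
#' @param w frequencies as fractions of Nyquist.
#' @return complex response at `w`.
#' @export
filter_response <- function(b, w) {
  k <- seq_along(b) - 1
  vapply(w, function(wi) sum(b * exp(-1i * pi * wi * k)), complex(1))
}

#' Low-pass filter calcium traces
#'
#' Applies the equiripple FIR filter row-wise. `phase = "compensated"`
#' (default) applies the causal filter and then removes the known linear
#' group delay so that event onsets stay aligned with the unfiltered
#' trace; `"causal"` keeps the raw single-pass output; `"zero"` uses
#' forward-backward filtering (zero phase, squared magnitude response).
#'
#' @param traces neurons x frames dF/F matrix.
#' @param b filter coefficients from [design_lowpass()].
#' @param phase one of `"compensated"`, `"causal"`, `"zero"`.
#' @return filtered matrix of the same shape.
#' @export
lowpass_filter <- function(traces, b = design_lowpass(),
                           phase = c("compensated", "causal", "zero")) {
  phase <- match.arg(phase)
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  if (!all(is.finite(traces))) stop("traces contain non-finite values")
  out <- matrix(0, nrow(traces), ncol(traces))
  gd <- round((length(b) - 1) / 2)
  for (i in seq_len(nrow(traces))) {
    x <- traces[i, ]
    if (phase == "zero") {
      y <- signal::filtfilt(b, 1, x)
    } else {
      y <- as.numeric(signal::filter(b, 1, x))
      if (phase == "compensated" && gd > 0)
        y <- c(y[-seq_len(gd)], rep(y[length(y)], gd))
    }
    out[i, ] <- y
  }
  out
}

#' Parameters for the calcium-transient detector
#'
#' @param derivative_min minimum one-frame rise of the filtered trace for
#'   a candidate event onset (dF/F per frame).
#' @param amplitude_min minimum peak deflection above baseline (dF/F).
#' @param auc_min minimum integrated area above baseline over the
#'   transient (dF/F x frames).
#' @return an object of class `event_params`.
#' @export
event_params <- function(derivative_min = 0.1,
                         amplitude_min = 0.15,
                         auc_min = 0.5) {
  stopifnot(derivative_min >= 0, amplitude_min >= 0, auc_min >= 0)
  structure(list(derivative_min = derivative_min,
                 amplitude_min = amplitude_min,
                 auc_min = auc_min),
            class = "event_params")
}

## Running 20th-percentile baseline over a window, evaluated on a coarse
## grid and linearly interpolated (the baseline varies slowly by
## construction).
running_baseline <- function(x, win, q = 0.2, grid_step = max(1L, win %/% 10L)) {
  n <- length(x)
  centers <- unique(c(seq(1L, n, by = grid_step), n))
  half <- win %/% 2L
  vals <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    stats::quantile(x[lo:hi], q, names = FALSE, type = 7)
  }, numeric(1))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Detect calcium transients and build a binary event raster
#'
#' Candidate onsets are frames where the first difference of the
#' (filtered) trace reaches `derivative_min`; consecutive candidate
#' frames collapse to one onset. A candidate is accepted when the
#' ensuing deflection above the running baseline (20th percentile over a
#' `baseline_win_s` window) reaches `amplitude_min` at its peak and
#' `auc_min` in integrated area before the trace returns to baseline or
#' a new onset begins. In `mode = "extent"` (default) the accepted
#' transient marks all frames from onset to return-to-baseline as
#' active, so downstream "fraction of frames active" statistics are
#' meaningful; `mode = "onset"` marks only the onset frame.
#'
#' @param traces neurons x frames dF/F matrix.
#' @param params an [event_params()].
#' @param frame_rate acquisition rate in Hz.
#' @param prefilter apply [lowpass_filter()] first (delay-compensated).
#' @param mode `"extent"` or `"onset"`.
#' @param baseline_win_s baseline window length in seconds.
#' @return an object of class `event_raster`: list with `values`
#'   (binary matrix per `mode`), `onsets` (list of onset frame indices
#'   per neuron, 1-based), and `frame_rate`.
#' @export
detect_events <- function(traces, params = event_params(), frame_rate = 20,
                          prefilter = TRUE,
                          mode = c("extent", "onset"),
                          baseline_win_s = 30) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "event_params"))
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  nan_rows <- which(apply(traces, 1, function(r) all(is.na(r))))
  if (length(nan_rows) > 0)
    stop("all-NaN trace for neuron(s): ", paste(nan_rows, collapse = ", "))
  x <- if (prefilter) lowpass_filter(traces) else traces
  n <- nrow(x); n_frames <- ncol(x)
  win <- max(3L, round(baseline_win_s * frame_rate))
  values <- matrix(0L, n, n_frames)
  onsets <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    d <- xi - running_baseline(xi, win)
    dx <- c(0, diff(xi))
    cand <- which(dx >= params$derivative_min)
    if (length(cand) == 0L) { onsets[[i]] <- integer(0); next }
    starts <- cand[c(TRUE, diff(cand) > 1L)]
    nonpos <- c(which(d <= 0), n_frames + 1L)
    cs <- cumsum(d)
    acc <- logical(length(starts))
    ends <- integer(length(starts))
    nxt <- c(starts[-1L] - 1L, n_frames)
    for (k in seq_along(starts)) {
      o <- starts[k]
      ret <- nonpos[findInterval(o, nonpos) + 1L] - 1L
      e <- min(ret, nxt[k], n_frames)
      if (e < o) e <- o
      seg <- d[o:e]
      peak <- max(seg)
      auc <- cs[e] - (if (o > 1L) cs[o - 1L] else 0)
      acc[k] <- peak >= params$amplitude_min && auc >= params$auc_min
      ends[k] <- e
    }
    ons <- starts[acc]
    onsets[[i]] <- ons
    if (mode == "onset") {
      values[i, ons] <- 1L
    } else {
      for (k in which(acc)) values[i, starts[k]:ends[k]] <- 1L
    }
  }
  structure(list(values = values, onsets = onsets, frame_rate = frame_rate,
                 params = params, mode = mode),
            class = "event_raster")
}

#' Frame extents of true events
#'
#' Expands ground-truth event onsets into the frames a transient
#' plausibly occupies (onset plus `n_tau` decay constants), used when
#' scoring frame-wise specificity.
#'
#' @param truth_raster binary onset raster (neurons x frames).
#' @param frame_rate Hz.
#' @param tau transient decay constant in seconds.
#' @param n_tau extent length in units of `tau`.
#' @return binary matrix of the same shape marking occupied frames.
#' @export
event_extents <- function(truth_raster, frame_rate = 20, tau = 0.5, n_tau = 3) {
  len <- ceiling(n_tau * tau * frame_rate)
  n_frames <- ncol(truth_raster)
  out <- matrix(0L, nrow(truth_raster), n_frames)
  for (i in seq_len(nrow(truth_raster))) {
    ev <- which(truth_raster[i, ] == 1L)
    for (o in ev) out[i, o:min(o + len, n_frames)] <- 1L
  }
  out
}

## Greedy one-to-one matching of detected to true onsets within +/- tol
## frames; returns the number of matched true onsets.
match_onsets <- function(detected, truth, tol = 2L) {
  if (length(truth) == 0L || length(detected) == 0L) return(0L)
  used <- logical(length(detected))
  hits <- 0L
  for (t in truth) {
    dd <- abs(detected - t)
    ok <- which(!used & dd <= tol)
    if (length(ok) > 0) {
      used[ok[which.min(dd[ok])]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

#' Sensitivity and specificity of a detection against ground truth
#'
#' Sensitivity: fraction of true onsets matched by a detected onset
#' within `tol` frames (one-to-one). Specificity: computed frame-wise on
#' frames outside the true-event extents; a frame counted active by the
#' detector outside every true extent is a false positive.
#'
#' @param detection an `event_raster` from [detect_events()].
#' @param truth_raster binary ground-truth onset raster.
#' @param tol onset matching tolerance in frames.
#' @param tau,n_tau passed to [event_extents()].
#' @return list with `sensitivity`, `specificity`, `n_true`, `n_detected`.
#'   With zero true events sensitivity is `NA` (undefined).
#' @export
detection_scores <- function(detection, truth_raster, tol = 2L,
                             tau = 0.5, n_tau = 3) {
  stopifnot(inherits(detection, "event_raster"),
            all(dim(detection$values) == dim(truth_raster)))
  ext <- event_extents(truth_raster, detection$frame_rate, tau, n_tau)
  hits <- 0L; n_true <- 0L
  for (i in seq_len(nrow(truth_raster))) {
    tr <- which(truth_raster[i, ] == 1L)
    n_true <- n_true + length(tr)
    hits <- hits + match_onsets(detection$onsets[[i]], tr, tol)
  }
  outside <- ext == 0L
  fp <- sum(detection$values == 1L & outside)
  spec <- 1 - fp / sum(outside)
  sens <- if (n_true == 0L) NA_real_ else hits / n_true
  list(sensitivity = sens, specificity = spec,
       n_true = n_true, n_detected = sum(lengths(detection$onsets)))
}

#' Tune detector thresholds against ground truth
#'
#' Evaluates every grid point and returns the one maximizing
#' min(sensitivity, specificity), with the full tuning report attached.
#' Traces are filtered once, outside the grid loop.
#'
#' @param traces dF/F matrix.
#' @param truth_raster binary ground-truth onset raster.
#' @param grid data frame with columns `derivative_min`, `amplitude_min`,
#'   `auc_min`.
#' @param frame_rate Hz.
#' @param tol onset matching tolerance in frames.
#' @param tau transient decay constant of the truth (seconds).
#' @return the selected [event_params()], with attributes `report`
#'   (data frame over the grid) and `scores` (the winning row).
#' @export
tune_detector <- function(traces, truth_raster, grid, frame_rate = 20,
                          tol = 2L, tau = 0.5) {
  if (NROW(grid) == 0L) stop("empty tuning grid")
  need <- c("derivative_min", "amplitude_min", "auc_min")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "))
  filt <- lowpass_filter(traces)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- event_params(grid$derivative_min[k], grid$amplitude_min[k],
                      grid$auc_min[k])
    det <- detect_events(filt, p, frame_rate, prefilter = FALSE)
    sc <- detection_scores(det, truth_raster, tol, tau)
    data.frame(grid[k, , drop = FALSE],
               sensitivity = sc$sensitivity,
               specificity = sc$specificity,
               n_detected = sc$n_detected)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  crit <- pmin(report$sensitivity, report$specificity)
  crit[is.na(crit)] <- report$specificity[is.na(crit)]
  best <- which.max(crit)
  out <- event_params(report$derivative_min[best],
                      report$amplitude_min[best],
                      report$auc_min[best])
  attr(out, "report") <- report
  attr(out, "scores") <- report[best, ]
  out
}

#' Z-score traces per neuron
#'
#' Centers and scales each neuron's trace to mean 0 and standard
#' deviation 1 over the whole session, using the population (divide by
#' n) convention. Constant traces cannot be scaled; they are returned as
#' zeros and flagged in the `excluded` attribute.
#'
#' @param traces neurons x frames matrix.
#' @return matrix of the same shape, attribute `excluded` = indices of
#'   constant (unscalable) neurons.
#' @export
zscore_traces <- function(traces) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  m <- rowMeans(traces)
  s <- sqrt(rowMeans((traces - m)^2))
  excluded <- which(s == 0)
  s[s == 0] <- 1
  out <- (traces - m) / s
  attr(out, "excluded") <- excluded
  out
}
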