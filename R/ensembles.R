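#' Frame masks from session annotations
#'
#' Helpers returning logical frame masks. The default nonsocial
#' definition covers every frame without active interaction, regardless
#' of whether the conspecific is present; the alternates restrict to the
#' alone period or to conspecific-present non-interacting frames.
#'
#' @param annotation a session annotation data frame.
#' @param epochs optional character vector of epoch ids restricting the
#'   mask.
#' @param definition nonsocial definition (see Details).
#' @return logical vector over frames.
#' @export
social_mask <- function(annotation, epochs = NULL) {
  m <- annotation$behavior %in% "social"
  if (!is.null(epochs)) m <- m & annotation$epoch_id %in% epochs
  m
}

#' @rdname social_mask
#' @export
nonsocial_mask <- function(annotation, epochs = NULL,
                           definition = c("all", "alone", "present")) {
  definition <- match.arg(definition)
  m <- switch(definition,
              all = annotation$behavior %in% c("alone", "present"),
              alone = annotation$behavior %in% "alone",
              present = annotation$behavior %in% "present")
  if (!is.null(epochs)) m <- m & annotation$epoch_id %in% epochs
  m
}

#' @rdname social_mask
#' @export
epoch_mask <- function(annotation, epochs) {
  annotation$epoch_id %in% epochs
}

#' @rdname social_mask
#' @param arms character vector of arm labels.
#' @export
arm_mask <- function(annotation, arms) {
  !is.na(annotation$arm) & annotation$arm %in% arms
}

#' Population activity vector for a condition
#'
#' Per-neuron mean activity over the masked frames: with a binary raster
#' this is the fraction of frames each neuron was active; with (z-scored)
#' traces it is the mean dF/F.
#'
#' @param x neurons x frames matrix (binary raster or traces).
#' @param mask logical or integer frame mask.
#' @param condition label used in error messages and stored on the
#'   result.
#' @return numeric vector of length `nrow(x)` with attributes
#'   `condition` and `n_frames`.
#' @export
population_vector <- function(x, mask, condition = "condition") {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0L)
    stop("empty frame mask for condition '", condition, "'")
  v <- rowMeans(x[, mask, drop = FALSE])
  attr(v, "condition") <- condition
  attr(v, "n_frames") <- length(mask)
  v
}

#' Activity summary across two conditions
#'
#' Per-condition activity fractions and counts of highly active
#' (fraction of frames active strictly greater than `threshold`,
#' default 7.5%) and inactive (zero events) neurons, plus the two-sample
#' Kolmogorov-Smirnov statistic between the condition-wise activity
#' distributions.
#'
#' @param raster binary neurons x frames matrix.
#' @param masks named list of two frame masks (e.g. social, nonsocial).
#' @param threshold highly-active cutoff on the fraction of frames
#'   (strict inequality).
#' @return list with `activity` (neurons x condition matrix), `summary`
#'   (per-condition counts), `ks` (statistic and p-value).
#' @export
activity_summary <- function(raster, masks, threshold = 0.075) {
  stopifnot(length(masks) == 2L, !is.null(names(masks)))
  act <- vapply(names(masks),
                function(nm) population_vector(raster, masks[[nm]], nm),
                numeric(nrow(raster)))
  summ <- data.frame(
    condition = colnames(act),
    n_frames = vapply(masks, function(m) sum(as.logical(m)), integer(1)),
    highly_active = colSums(act > threshold),
    inactive = colSums(act == 0),
    mean_activity = colMeans(act)
  )
  rownames(summ) <- NULL
  ks <- suppressWarnings(stats::ks.test(act[, 1], act[, 2]))
  list(activity = act, summary = summ,
       ks = list(statistic = unname(ks$statistic), p.value = ks$p.value))
}

#' Pairwise Pearson similarity between population vectors
#'
#' @param vectors named list of equal-length population vectors.
#' @return a symmetric correlation matrix of class `similarity_matrix`
#'   with unit diagonal. Requires at least two non-constant vectors;
#'   constant vectors yield `NA` rows/columns with a warning.
#' @export
similarity_matrix <- function(vectors) {
  if (length(vectors) < 2L) stop("need at least 2 population vectors")
  len <- unique(lengths(vectors))
  if (length(len) != 1L) stop("population vectors have unequal lengths")
  m <- do.call(cbind, vectors)
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (sum(!const) < 2L)
    stop("need at least 2 non-constant vectors to correlate")
  if (any(const))
    warning("constant population vector(s): ",
            paste(colnames(m)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  class(r) <- c("similarity_matrix", class(r))
  r
}

#' Mean similarity within and between contexts
#'
#' Averages the off-diagonal similarity entries over pairs of epochs in
#' the same context vs pairs in different contexts, separately for
#' same-type pairs (social-social, nonsocial-nonsocial) and cross-type
#' pairs. Vector keys are taken from `keys`, a data frame aligned with
#' the similarity matrix rows giving each vector's `epoch` and `type`.
#'
#' @param sim a [similarity_matrix()].
#' @param keys data frame with columns `epoch` and `type`, one row per
#'   vector in `sim`.
#' @param context_map named character vector mapping epoch to context.
#' @return data frame with columns `type_pair`, `relation`
#'   (within/between), `mean_r`, `n_pairs`. A context with fewer than two
#'   epochs yields `NA` for its within mean.
#' @export
within_between_summary <- function(sim, keys, context_map) {
  stopifnot(nrow(keys) == nrow(sim),
            all(c("epoch", "type") %in% names(keys)))
  ctx <- unname(context_map[keys$epoch])
  if (any(is.na(ctx))) stop("context_map missing epochs: ",
                            paste(unique(keys$epoch[is.na(ctx)]), collapse = ", "))
  n <- nrow(sim)
  rows <- list()
  pairs <- which(upper.tri(sim), arr.ind = TRUE)
  tp <- apply(pairs, 1, function(ij) {
    t1 <- keys$type[ij[1]]; t2 <- keys$type[ij[2]]
    paste(sort(c(t1, t2)), collapse = "-")
  })
  same_epoch <- keys$epoch[pairs[, 1]] == keys$epoch[pairs[, 2]]
  rel <- ifelse(ctx[pairs[, 1]] == ctx[pairs[, 2]], "within", "between")
  ## same-epoch same-type pairs are the diagonal (excluded already);
  ## same-epoch cross-type pairs stay, matching within-context usage
  vals <- sim[pairs]
  for (t in unique(tp)) {
    for (r in c("within", "between")) {
      sel <- tp == t & rel == r
      rows[[length(rows) + 1L]] <- data.frame(
        type_pair = t, relation = r,
        mean_r = if (any(sel)) mean(vals[sel]) else NA_real_,
        n_pairs = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neurons active in both contexts
#'
#' @param raster binary neurons x frames matrix.
#' @param annotation session annotation.
#' @return integer vector of neuron indices with at least one event in
#'   every context present in the annotation.
#' @export
filter_active_both <- function(raster, annotation) {
  contexts <- unique(annotation$context_id)
  if (length(contexts) < 2L)
    stop("need at least two contexts; found: ",
         paste(contexts, collapse = ", "))
  active <- vapply(contexts, function(cx) {
    rowSums(raster[, annotation$context_id == cx, drop = FALSE]) > 0
  }, logical(nrow(raster)))
  which(rowSums(active) == length(contexts))
}
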