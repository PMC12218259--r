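#' Degree-preserving surrogate raster
#'
#' Randomly reassigns the neuron identity of individual calcium events
#' so that both the number of events in each frame (column sums) and the
#' number of events assigned to each neuron (row sums) are unchanged.
#' Implemented as a checkerboard-swap Markov chain: two events trade
#' columns whenever the trade keeps the matrix binary. The default chain
#' length is 10 successful swaps per event. Degenerate matrices with a
#' unique margin configuration are returned unchanged.
#'
#' @param raster binary neurons x frames matrix.
#' @param seed integer seed (optional).
#' @param swaps_per_event successful swaps per event (chain length).
#' @return binary matrix with identical row and column sums.
#' @export
surrogate_shuffle <- function(raster, seed = NULL, swaps_per_event = 10) {
  if (!is.null(seed)) set.seed(seed)
  storage.mode(raster) <- "integer"
  ne <- sum(raster)
  ## odd/even chain lengths both occur, so small state spaces are not
  ## trapped on one parity class
  n_swaps <- ceiling(swaps_per_event * ne) + sample(0:1, 1L)
  .checkerboard_swap(raster, n_swaps)
}

#' Classification metrics from confusion counts
#'
#' Precision = TP / (TP + FP); Recall = TP / (TP + FN);
#' F1 = 2 x Precision x Recall / (Precision + Recall). Undefined ratios
#' (zero denominators) are returned as `NA`, never silently as 0.
#'
#' @param tp,fp,fn,tn confusion counts (non-negative).
#' @return named list: `precision`, `recall`, `f1`, `accuracy` (the
#'   latter `NA` when `tn` is not supplied).
#' @export
classification_metrics <- function(tp, fp, fn, tn = NA) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else NA_real_
  accuracy <- if (!is.na(tn)) (tp + tn) / (tp + fp + fn + tn) else NA_real_
  list(precision = precision, recall = recall, f1 = f1, accuracy = accuracy)
}

#' Define a decoding task
#'
#' @param pos_mask,neg_mask disjoint frame masks (logical or indices)
#'   for the positive (e.g. social) and negative class.
#' @param n_iterations resampling iterations.
#' @param holdout held-out fraction when training and testing on the
#'   same scope (must lie in (0, 1)).
#' @param max_per_class cap on frames sampled per class per iteration
#'   (keeps the fit tractable; class balance is preserved).
#' @param seed integer seed.
#' @return an object of class `decode_task`.
#' @export
decode_task <- function(pos_mask, neg_mask, n_iterations = 500L,
                        holdout = 0.25, max_per_class = 1000L,
                        seed = NULL) {
  if (is.logical(pos_mask)) pos_mask <- which(pos_mask)
  if (is.logical(neg_mask)) neg_mask <- which(neg_mask)
  if (length(intersect(pos_mask, neg_mask)) > 0)
    stop("positive and negative masks overlap")
  stopifnot(holdout > 0, holdout < 1, n_iterations >= 1)
  structure(list(pos = pos_mask, neg = neg_mask,
                 n_iterations = as.integer(n_iterations),
                 holdout = holdout,
                 max_per_class = max_per_class,
                 seed = seed),
            class = "decode_task")
}

## Fit one linear max-margin classifier (hinge loss, cost 1) and return
## the fit plus its weight vector over neurons.
fit_linear_svm <- function(X, y) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = 1,
                    scale = FALSE, type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  list(fit = fit, w = w)
}

confusion <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Train and evaluate a balanced linear decoder
#'
#' On each iteration the majority class is downsampled to match the
#' minority class, a fraction `holdout` of each class is held out, a
#' linear max-margin classifier (hinge loss, regularization constant 1)
#' is fit on the remainder using raw binary frame vectors as features,
#' and accuracy, precision, recall, and F1 are measured on the held-out
#' frames. Because the held-out set is balanced per class, chance
#' accuracy is exactly 50%.
#'
#' @param raster binary neurons x frames matrix (features are columns).
#' @param task a [decode_task()].
#' @return object of class `decode_result`: list with `summary` (mean
#'   and sd of each metric over iterations), `accuracy` (per-iteration
#'   vector), and `beta` (mean weight vector over iterations).
#' @export
train_eval <- function(raster, task) {
  stopifnot(inherits(task, "decode_task"))
  if (!is.null(task$seed)) set.seed(task$seed)
  pos <- task$pos; neg <- task$neg
  if (length(pos) == 0L || length(neg) == 0L)
    stop("a class has zero frames")
  n_class <- min(length(pos), length(neg), task$max_per_class)
  if (n_class < 10L)
    warning("fewer than 10 frames per class (", n_class, ")")
  n_test <- max(1L, round(task$holdout * n_class))
  acc <- prec <- rec <- f1 <- numeric(task$n_iterations)
  beta_sum <- numeric(nrow(raster))
  for (it in seq_len(task$n_iterations)) {
    p <- sample(pos, n_class)
    q <- sample(neg, n_class)
    p_test <- seq_len(n_test); q_test <- seq_len(n_test)
    tr_frames <- c(p[-p_test], q[-q_test])
    te_frames <- c(p[p_test], q[q_test])
    y_tr <- factor(rep(c("pos", "neg"), each = n_class - n_test),
                   levels = c("neg", "pos"))
    y_te <- factor(rep(c("pos", "neg"), each = n_test),
                   levels = c("neg", "pos"))
    mdl <- fit_linear_svm(t(raster[, tr_frames, drop = FALSE]), y_tr)
    pred <- stats::predict(mdl$fit, t(raster[, te_frames, drop = FALSE]))
    cf <- confusion(pred, y_te, "pos")
    m <- classification_metrics(cf["tp"], cf["fp"], cf["fn"], cf["tn"])
    acc[it] <- m$accuracy
    prec[it] <- m$precision; rec[it] <- m$recall; f1[it] <- m$f1
    ## svm decision values favor the first class of the fitted pair;
    ## orient weights so positive values favor the positive class
    first <- mdl$fit$levels[mdl$fit$labels[1]]
    wsign <- if (identical(first, "pos")) 1 else -1
    beta_sum <- beta_sum + wsign * mdl$w
  }
  structure(list(
    summary = data.frame(
      metric = c("accuracy", "precision", "recall", "f1"),
      mean = c(mean(acc), mean(prec, na.rm = TRUE),
               mean(rec, na.rm = TRUE), mean(f1, na.rm = TRUE)),
      sd = c(stats::sd(acc), stats::sd(prec), stats::sd(rec),
             stats::sd(f1))),
    accuracy = acc,
    beta = beta_sum / task$n_iterations,
    n_per_class = n_class,
    n_iterations = task$n_iterations),
    class = "decode_result")
}

#' Cross-scope decoder transfer
#'
#' Trains on all frames of the training scope (balanced by downsampling
#' each iteration) and tests on balanced samples from each disjoint test
#' scope. Balanced test sampling makes 50% the exact chance level.
#'
#' @param raster binary neurons x frames matrix.
#' @param train_masks list of two frame masks (positive, negative) in
#'   the training scope.
#' @param test_masks named list of test scopes, each a list of two frame
#'   masks (positive, negative); frames must be disjoint from training
#'   frames.
#' @param n_iterations iterations (default 200).
#' @param max_per_class cap on frames per class per iteration.
#' @param seed integer seed.
#' @return data frame with one row per test scope: `test`, `mean_acc`,
#'   `sd_acc`, `precision`, `recall`, `f1`.
#' @export
transfer_eval <- function(raster, train_masks, test_masks,
                          n_iterations = 200L, max_per_class = 1000L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_idx <- function(m) if (is.logical(m)) which(m) else m
  trp <- as_idx(train_masks[[1]]); trn <- as_idx(train_masks[[2]])
  if (length(intersect(trp, trn)) > 0) stop("training masks overlap")
  test_masks <- lapply(test_masks, function(tm) lapply(tm, as_idx))
  tr_all <- c(trp, trn)
  for (nm in names(test_masks)) {
    te_all <- unlist(test_masks[[nm]])
    if (length(intersect(tr_all, te_all)) > 0)
      stop("test scope '", nm, "' overlaps the training frames")
  }
  if (length(trp) == 0L || length(trn) == 0L)
    stop("a training class has zero frames")
  n_tr <- min(length(trp), length(trn), max_per_class)
  res <- array(NA_real_, c(length(test_masks), n_iterations, 4),
               dimnames = list(names(test_masks), NULL,
                               c("acc", "prec", "rec", "f1")))
  for (it in seq_len(n_iterations)) {
    y_tr <- factor(rep(c("pos", "neg"), each = n_tr),
                   levels = c("neg", "pos"))
    tr_frames <- c(sample(trp, n_tr), sample(trn, n_tr))
    mdl <- fit_linear_svm(t(raster[, tr_frames, drop = FALSE]), y_tr)
    for (nm in names(test_masks)) {
      tp_ <- test_masks[[nm]][[1]]; tn_ <- test_masks[[nm]][[2]]
      if (length(tp_) == 0L || length(tn_) == 0L) next
      n_te <- min(length(tp_), length(tn_), max_per_class)
      te_frames <- c(sample(tp_, n_te), sample(tn_, n_te))
      y_te <- factor(rep(c("pos", "neg"), each = n_te),
                     levels = c("neg", "pos"))
      pred <- stats::predict(mdl$fit, t(raster[, te_frames, drop = FALSE]))
      cf <- confusion(pred, y_te, "pos")
      m <- classification_metrics(cf["tp"], cf["fp"], cf["fn"], cf["tn"])
      res[nm, it, ] <- c(m$accuracy, m$precision, m$recall, m$f1)
    }
  }
  out <- data.frame(
    test = names(test_masks),
    mean_acc = apply(res[, , "acc", drop = FALSE], 1, mean, na.rm = TRUE),
    sd_acc = apply(res[, , "acc", drop = FALSE], 1, stats::sd, na.rm = TRUE),
    precision = apply(res[, , "prec", drop = FALSE], 1, mean, na.rm = TRUE),
    recall = apply(res[, , "rec", drop = FALSE], 1, mean, na.rm = TRUE),
    f1 = apply(res[, , "f1", drop = FALSE], 1, mean, na.rm = TRUE))
  rownames(out) <- NULL
  out
}

#' Correlation between decoder weights and modulation indices
#'
#' Pearson correlation between the mean SVM weight assigned to each
#' neuron and its modulation index, over the shared non-excluded neuron
#' set.
#'
#' @param result a `decode_result` from [train_eval()].
#' @param modvec a `mod_vector`.
#' @return Pearson r.
#' @export
weight_modulation_correlation <- function(result, modvec) {
  stopifnot(inherits(result, "decode_result"),
            inherits(modvec, "mod_vector"))
  keep <- !modvec$excluded & !is.na(modvec$index)
  if (sum(keep) < 3L) stop("fewer than 3 shared neurons")
  stats::cor(result$beta[modvec$neuron[keep]], modvec$index[keep])
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result> ", x$n_iterations, " iterations, ",
      x$n_per_class, " frames/class\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
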