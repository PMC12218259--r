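## Align two mod_vectors on their shared non-excluded neuron set.
align_mod_vectors <- function(v1, v2) {
  stopifnot(inherits(v1, "mod_vector"), inherits(v2, "mod_vector"))
  ok1 <- !v1$excluded & !is.na(v1$index)
  ok2 <- !v2$excluded & !is.na(v2$index)
  shared <- intersect(v1$neuron[ok1], v2$neuron[ok2])
  list(a = v1$index[match(shared, v1$neuron)],
       b = v2$index[match(shared, v2$neuron)],
       neurons = shared)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Similarity between two modulation vectors with a permutation null
#'
#' The default metric is the cosine similarity of the zero-centered
#' index vectors, where zero-centering subtracts 50 -- the null
#' expectation of a percentile index -- so that unmodulated neurons
#' contribute nothing to either vector. `metric = "pearson"` instead
#' mean-centers each vector (ordinary correlation). The null
#' distribution is obtained by randomly re-assigning the neuron
#' associated with each index value of the second vector
#' (entry permutation), and the observed value is reported as a
#' mid-rank percentile of that null.
#'
#' @param v1,v2 `mod_vector`s (aligned on their shared non-excluded
#'   neurons; at least 3 required).
#' @param metric `"cosine"` (zero-centered at 50) or `"pearson"`.
#' @param n_permutations permutation draws for the null.
#' @param seed integer seed.
#' @return list of class `similarity_report`: `observed`, `null_mean`,
#'   `null_sd`, `percentile`, `n_neurons`, `metric`. `observed` is `NA`
#'   (undefined) when a centered vector is all zeros.
#' @export
vector_similarity <- function(v1, v2, metric = c("cosine", "pearson"),
                              n_permutations = 10000L, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  al <- align_mod_vectors(v1, v2)
  if (length(al$neurons) < 3L)
    stop("fewer than 3 shared non-excluded neurons")
  center <- function(v) if (metric == "cosine") v - 50 else v - mean(v)
  a <- center(al$a); b <- center(al$b)
  observed <- cosine_sim(a, b)
  null <- vapply(seq_len(n_permutations), function(k) {
    bp <- b[sample.int(length(b))]
    if (metric == "pearson") bp <- bp - mean(bp)
    cosine_sim(a, bp)
  }, numeric(1))
  null <- null[is.finite(null)]
  pct <- if (is.na(observed) || length(null) == 0L) NA_real_ else
    100 * (sum(null < observed) + 0.5 * sum(null == observed)) / length(null)
  structure(list(observed = observed,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 percentile = pct,
                 n_neurons = length(al$neurons),
                 n_permutations = n_permutations,
                 metric = metric),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> ", x$metric, " = ",
      formatC(x$observed, digits = 3, format = "f"),
      " (null ", formatC(x$null_mean, digits = 3, format = "f"), " +/- ",
      formatC(x$null_sd, digits = 3, format = "f"),
      "; percentile ", formatC(x$percentile, digits = 1, format = "f"),
      "; n = ", x$n_neurons, ")\n", sep = "")
  invisible(x)
}

#' Pairwise similarity reports for a set of modulation vectors
#'
#' Computes [vector_similarity()] for every pair, using the pairwise
#' intersection of non-excluded neurons, and returns observed,
#' null-expected (mean of the permutation null), and percentile
#' matrices. The shuffled matrix mirrors the real one with permuted
#' neuron assignments, so its off-diagonal structure is destroyed.
#'
#' @param vectors named list of `mod_vector`s.
#' @inheritParams vector_similarity
#' @return list with matrices `observed`, `null_mean`, `percentile`,
#'   and `difference` (observed minus null mean).
#' @export
similarity_report_matrix <- function(vectors, metric = c("cosine", "pearson"),
                                     n_permutations = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  k <- length(vectors)
  stopifnot(k >= 2L, !is.null(names(vectors)))
  nm <- names(vectors)
  obs <- nullm <- pct <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(obs) <- 1; diag(pct) <- 100; diag(nullm) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      rep_ <- vector_similarity(vectors[[i]], vectors[[j]], metric,
                                n_permutations)
      obs[i, j] <- obs[j, i] <- rep_$observed
      nullm[i, j] <- nullm[j, i] <- rep_$null_mean
      pct[i, j] <- pct[j, i] <- rep_$percentile
    }
  }
  list(observed = obs, null_mean = nullm, percentile = pct,
       difference = obs - nullm, metric = metric)
}

#' 3x3 overlap table of two modulation vectors
#'
#' Classifies each shared neuron as strongly positively modulated
#' (index > 90, strict), strongly negatively modulated (index < 10,
#' strict), or non-modulated (10-90), on each vector, and tabulates the
#' 3x3 joint counts.
#'
#' @param v1,v2 `mod_vector`s.
#' @param hi,lo percentile cutoffs (strict inequalities).
#' @return 3x3 integer matrix of class `overlap_table` (rows = `v1`
#'   categories, columns = `v2`), with attribute `n` = total neurons.
#' @export
overlap_table <- function(v1, v2, hi = 90, lo = 10) {
  al <- align_mod_vectors(v1, v2)
  cls <- function(v) factor(ifelse(v > hi, "positive",
                            ifelse(v < lo, "negative", "middle")),
                            levels = c("positive", "middle", "negative"))
  tab <- table(cls(al$a), cls(al$b))
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- NULL
  attr(out, "n") <- length(al$neurons)
  class(out) <- c("overlap_table", class(out))
  out
}

#' Compare one overlap cell between two tables
#'
#' Builds the 2x2 contingency table (in-cell vs not, table A vs table B)
#' and applies Pearson's chi-squared test without continuity correction
#' (toggle via `correct`).
#'
#' @param tableA,tableB `overlap_table`s.
#' @param cell length-2 character vector naming the row and column
#'   category (e.g. `c("positive", "positive")`), or a single index.
#' @param correct apply Yates continuity correction.
#' @return list: `statistic`, `p.value`, `proportions` (per table),
#'   `counts`, and `warning` flag when an expected count is below 1.
#' @export
compare_overlap <- function(tableA, tableB, cell = c("positive", "positive"),
                            correct = FALSE) {
  stopifnot(inherits(tableA, "overlap_table"),
            inherits(tableB, "overlap_table"))
  nA <- attr(tableA, "n"); nB <- attr(tableB, "n")
  if (nA <= 0 || nB <= 0) stop("overlap tables must have positive n")
  a <- tableA[cell[1], cell[2]]
  b <- tableB[cell[1], cell[2]]
  m <- matrix(c(a, nA - a, b, nB - b), 2, 2,
              dimnames = list(c("in_cell", "out"), c("A", "B")))
  expect <- outer(rowSums(m), colSums(m)) / sum(m)
  low <- any(expect < 1)
  if (low) warning("expected count below 1 in the 2x2 comparison")
  ct <- if (a == b && nA == nB) {
    list(statistic = c(`X-squared` = 0), p.value = 1)
  } else {
    suppressWarnings(stats::chisq.test(m, correct = correct))
  }
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       proportions = c(A = a / nA, B = b / nB),
       counts = m, low_expected = low)
}
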