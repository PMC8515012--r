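# Discrete information-theoretic evaluation: equipopulated binning,
# bias-corrected mutual information, pointwise common-surprisal redundancy,
# and permutation noise thresholds. All estimators are deterministic given
# the binned labels.

#' Equipopulated binning
#'
#' Rank-based quantile discretization into `B` bins with equal counts up to
#' +/- 1 when values are distinct. Tied values always share a bin (ties get
#' the minimum rank), so heavily tied data yield unequal counts by design.
#'
#' @param x numeric vector, length >= B, non-constant.
#' @param B number of bins (default 3).
#' @return object of class `binned_variable`: list with `labels` (integers
#'   0..B-1), `B`, `bin_edges` (empirical quantiles, reporting only).
#' @export
bin_equipopulated <- function(x, B = 3L) {
  n <- length(x)
  if (n < B) stop("need at least B = ", B, " observations")
  if (length(unique(x)) == 1L) stop("constant input: binning undefined")
  r <- rank(x, ties.method = "min")
  labels <- as.integer(ceiling(r * B / n)) - 1L
  labels[labels < 0L] <- 0L
  structure(list(labels = labels, B = as.integer(B),
                 bin_edges = unname(stats::quantile(x, (1:(B - 1)) / B))),
            class = "binned_variable")
}

as_labels <- function(x) {
  if (inherits(x, "binned_variable")) x$labels else as.integer(x)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Miller-Madow corrected mutual information
#'
#' Plug-in MI from the empirical contingency table, with each entropy term
#' given the Miller-Madow bias correction (K_occupied - 1) / (2 n ln 2),
#' where K_occupied counts occupied cells only. Symmetric in its arguments.
#'
#' @param x,y `binned_variable`s (or integer label vectors) of equal length.
#' @return mutual information in bits (can be slightly negative after
#'   correction under independence).
#' @export
mutual_information_mm <- function(x, y) {
  lx <- as_labels(x); ly <- as_labels(y)
  n <- length(lx)
  if (n == 0L) stop("empty input")
  if (length(ly) != n) stop("x and y must have equal length")
  tab <- table(lx, ly)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  mm <- function(k) (k - 1) / (2 * n * log(2))
  hx <- entropy_bits(px) + mm(sum(px > 0))
  hy <- entropy_bits(py) + mm(sum(py > 0))
  hxy <- entropy_bits(as.vector(pxy)) + mm(sum(pxy > 0))
  hx + hy - hxy
}

plugin_mi_bits <- function(lx, ly) {
  n <- length(lx)
  pxy <- table(lx, ly) / n
  entropy_bits(rowSums(pxy)) + entropy_bits(colSums(pxy)) -
    entropy_bits(as.vector(pxy))
}

# Iterative proportional fitting of a 3-way table to three pairwise margins
# (1,3), (2,3), (1,2). Returns the maximum-entropy joint with those margins.
# Margins inconsistent with a strictly positive joint make IPF converge only
# like 1/iteration; the stopping rule (tolerance, cap, update order) is part
# of the normative definition and mirrored by the test oracle.
ipf_pairwise <- function(p, tol = 1e-10, max_iter = 5000L) {
  q <- array(1 / length(p), dim = dim(p))
  m13 <- apply(p, c(1L, 3L), sum)
  m23 <- apply(p, c(2L, 3L), sum)
  m12 <- apply(p, c(1L, 2L), sum)
  adjust <- function(q, target, margins) {
    cur <- apply(q, margins, sum)
    ratio <- ifelse(cur > 0, target / cur, 0)
    sweep(q, margins, ratio, "*")
  }
  for (it in seq_len(max_iter)) {
    q <- adjust(q, m13, c(1L, 3L))
    q <- adjust(q, m23, c(2L, 3L))
    q <- adjust(q, m12, c(1L, 2L))
    err <- max(abs(apply(q, c(1L, 3L), sum) - m13),
               abs(apply(q, c(2L, 3L), sum) - m23),
               abs(apply(q, c(1L, 2L), sum) - m12))
    if (err < tol) break
  }
  q
}

#' Redundancy via pointwise common change in surprisal
#'
#' Partial-information-decomposition redundancy between two discrete sources
#' about a target. The joint distribution is replaced by the maximum-entropy
#' distribution consistent with the (s1, t), (s2, t) and (s1, s2) pairwise
#' marginals (fitted by iterative proportional fitting); at each joint state
#' the local co-information
#' `c = i(s1; t) + i(s2; t) - i(s1, s2; t)` is accumulated only where both
#' sources' local informations about the target and `c` itself are positive.
#' The result is clamped to `[0, min(I(s1; t), I(s2; t))]`.
#'
#' @param s1,s2 source `binned_variable`s (or label vectors).
#' @param t target `binned_variable` (or label vector).
#' @return redundancy in bits.
#' @export
redundancy_iccs <- function(s1, s2, t) {
  l1 <- as_labels(s1); l2 <- as_labels(s2); lt <- as_labels(t)
  n <- length(lt)
  if (n == 0L) stop("empty input")
  if (length(l1) != n || length(l2) != n) stop("unequal lengths")
  a1 <- sort(unique(l1)); a2 <- sort(unique(l2)); at <- sort(unique(lt))
  p <- array(0, dim = c(length(a1), length(a2), length(at)))
  idx <- cbind(match(l1, a1), match(l2, a2), match(lt, at))
  for (r in seq_len(n)) p[idx[r, 1L], idx[r, 2L], idx[r, 3L]] <-
      p[idx[r, 1L], idx[r, 2L], idx[r, 3L]] + 1 / n

  q <- ipf_pairwise(p)
  p1 <- apply(q, 1L, sum); p2 <- apply(q, 2L, sum); pt <- apply(q, 3L, sum)
  p13 <- apply(q, c(1L, 3L), sum)
  p23 <- apply(q, c(2L, 3L), sum)
  p12 <- apply(q, c(1L, 2L), sum)

  red <- 0
  for (i in seq_along(a1)) for (j in seq_along(a2)) for (k in seq_along(at)) {
    pj <- q[i, j, k]
    if (pj <= 0) next
    if (p13[i, k] <= 0 || p23[j, k] <= 0 || p12[i, j] <= 0) next
    i1 <- log2(p13[i, k] / (p1[i] * pt[k]))
    i2 <- log2(p23[j, k] / (p2[j] * pt[k]))
    i12 <- log2(pj / (p12[i, j] * pt[k]))
    cc <- i1 + i2 - i12
    if (i1 > 0 && i2 > 0 && cc > 0) red <- red + pj * cc
  }
  upper <- min(plugin_mi_bits(l1, lt), plugin_mi_bits(l2, lt))
  min(max(red, 0), upper)
}

#' Permutation noise threshold
#'
#' Applies an evaluation function to `n_perm` trial-shuffled copies of the
#' response vector and returns the requested percentile of the resulting
#' null distribution, the standard noise threshold for information
#' estimates.
#'
#' @param eval_fn function(ratings) -> scalar statistic.
#' @param ratings numeric/integer response vector to shuffle.
#' @param n_perm number of permutations (>= 20).
#' @param percentile percentile of the null (default 95).
#' @param seed integer seed; the permutation stream is reproducible.
#' @return threshold (scalar); attribute `null` holds all permuted values.
#' @export
permutation_null <- function(eval_fn, ratings, n_perm = 100L,
                             percentile = 95, seed = 1L) {
  if (n_perm < 20L) stop("n_perm must be >= 20")
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(b) {
    out <- tryCatch(eval_fn(sample(ratings)), error = function(e)
      stop("eval_fn failed at permutation ", b, ": ", conditionMessage(e)))
    as.numeric(out)
  }, numeric(1))
  thr <- unname(stats::quantile(vals, percentile / 100))
  attr(thr, "null") <- vals
  thr
}

#' Fraction of values exceeding their noise thresholds
#'
#' @param values numeric vector of statistics.
#' @param thresholds matching thresholds (scalar recycled).
#' @return fraction in `[0, 1]` of strict exceedances.
#' @export
exceedance_fraction <- function(values, thresholds) {
  if (length(values) == 0L) stop("empty input")
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, length(values))
  if (length(thresholds) != length(values)) stop("length mismatch")
  mean(values > thresholds)
}
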