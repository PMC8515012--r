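# Reverse correlation: reconstruct internal templates from observed or
# model-predicted choose-and-rate behavior by mass-univariate regression of
# stimulus features on responses, then amplification tuning of the slopes.

#' Model choices from an array of candidates
#'
#' Given predicted ratings for every stimulus, picks per trial the candidate
#' with the highest prediction (ties broken toward the lowest candidate
#' index, counted in the `n_ties` attribute).
#'
#' @param predictions numeric vector, one prediction per stimulus.
#' @param arrays integer matrix (trials x array size) of stimulus indices.
#' @return list with `chosen_col` (position within the array),
#'   `chosen_stimulus` (stimulus index) and `chosen_prediction`;
#'   attribute `n_ties`.
#' @export
choose_faces <- function(predictions, arrays) {
  if (anyNA(predictions[arrays]))
    stop("missing prediction for stimuli in trial ",
         which(rowSums(is.na(matrix(predictions[arrays], nrow(arrays)))) > 0)[1L])
  P <- matrix(predictions[t(arrays)], nrow = nrow(arrays),
              ncol = ncol(arrays), byrow = TRUE)
  chosen <- max.col(P, ties.method = "first")
  rowmax <- P[cbind(seq_len(nrow(P)), chosen)]
  n_ties <- sum(rowSums(P == rowmax) > 1L)
  if (n_ties > 0L) message(n_ties, " trial(s) had tied maxima; ",
                           "lowest candidate index chosen")
  out <- list(chosen_col = chosen,
              chosen_stimulus = arrays[cbind(seq_len(nrow(arrays)), chosen)],
              chosen_prediction = rowmax)
  attr(out, "n_ties") <- n_ties
  out
}

bisquare_irls <- function(x, y, c_tuning = 4.685, max_iter = 50L) {
  # simple regression y-on-x by iteratively reweighted least squares
  w <- rep(1, length(x))
  b <- c(mean(y), 0)
  for (it in seq_len(max_iter)) {
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    vxx <- sum(w * (x - mx)^2)
    b_new <- if (vxx > 0) c(NA, sum(w * (x - mx) * (y - my)) / vxx) else c(my, 0)
    if (vxx > 0) b_new[1] <- my - b_new[2] * mx
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
    r <- y - b[1] - b[2] * x
    s <- stats::median(abs(r)) / 0.6745
    if (s == 0) break
    u <- r / (c_tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) { w <- rep(1, length(x)); break }
  }
  b
}

#' Mass-univariate reverse-correlation fit
#'
#' Regresses each stimulus feature (vertex coordinate or texture value) of
#' the chosen faces on the observed or predicted responses:
#' `feature = b0 + b1 * rating`. The default estimator is ordinary least
#' squares (vectorized across coordinates); a robust bisquare variant
#' (tuning constant 4.685, 50 iterations) is available.
#'
#' @param chosen_features n_trials x D matrix of chosen-face features.
#' @param ratings responses, length n_trials (>= 3), non-constant.
#' @param method `"ols"` (default) or `"robust"`.
#' @return object of class `revcor_fit`: `b0`, `b1` (length D each).
#' @export
mass_univariate_fit <- function(chosen_features, ratings,
                                method = c("ols", "robust")) {
  method <- match.arg(method)
  Fm <- as.matrix(chosen_features)
  n <- nrow(Fm)
  if (n < 3L) stop("need at least 3 trials")
  if (length(ratings) != n) stop("ratings length mismatch")
  if (stats::var(ratings) == 0) stop("ratings are constant")
  if (method == "ols") {
    r <- ratings - mean(ratings)
    b1 <- drop(crossprod(Fm, r)) / sum(r^2)
    b0 <- colMeans(Fm) - b1 * mean(ratings)
  } else {
    est <- apply(Fm, 2L, function(col) bisquare_irls(ratings, col))
    b0 <- est[1L, ]; b1 <- est[2L, ]
  }
  structure(list(b0 = unname(b0), b1 = unname(b1), method = method, n = n),
            class = "revcor_fit")
}

#' Amplification tuning curve
#'
#' Builds faces `face(alpha) = b0 + alpha * b1` along the reverse-correlation
#' slope field (alpha = 0 is the average chosen face, the intercept-only
#' reconstruction), evaluates a responder on each, and takes the first
#' maximum of the response curve as the peak amplification.
#'
#' @param revcor a `revcor_fit`.
#' @param responder function mapping a flat face vector to a scalar
#'   predicted response.
#' @param amp_grid amplification levels (default 0 to 50 in steps of 0.5).
#' @return object of class `tuning_curve`: `amplifications`, `responses`,
#'   `peak_amp`, `peak_face`; attribute `n_ties` counts tied maxima.
#' @export
amplification_tuning <- function(revcor, responder,
                                 amp_grid = seq(0, 50, by = 0.5)) {
  if (length(amp_grid) == 0L) stop("empty amplification grid")
  resp <- vapply(amp_grid, function(a) responder(revcor$b0 + a * revcor$b1),
                 numeric(1))
  peak_i <- which.max(resp)  # first maximum on ties
  n_ties <- sum(resp == resp[peak_i]) - 1L
  if (n_ties > 0L) message("tuning curve has ", n_ties + 1L,
                           " tied maxima; first taken")
  structure(list(amplifications = amp_grid, responses = resp,
                 peak_amp = amp_grid[peak_i],
                 peak_face = revcor$b0 + amp_grid[peak_i] * revcor$b1,
                 n_ties = n_ties),
            class = "tuning_curve")
}

#' Template quality metrics
#'
#' Mean absolute coordinate error between a reconstructed template and a
#' reference face, and the correlation of their per-vertex inward-outward
#' displacements: displacements from the prototype are projected onto the
#' prototype's outward vertex normals and correlated across vertices
#' (Pearson). Used both for "veridicality" (reference = ground truth) and
#' "humanness" (reference = the observer's own recovered template).
#'
#' @param template,reference flat V*3 vectors.
#' @param prototype flat V*3 categorical-average face.
#' @param normals optional V x 3 outward normals (default
#'   [vertex_normals()] of the prototype).
#' @return list with `mae` and `r_inout` (`NA_real_` when either projection
#'   field has zero variance).
#' @export
template_metrics <- function(template, reference, prototype, normals = NULL) {
  stopifnot(length(template) == length(reference),
            length(template) == length(prototype))
  if (is.null(normals)) normals <- vertex_normals(prototype)
  mae <- mean(abs(template - reference))
  proj <- function(x) {
    D <- matrix(x - prototype, ncol = 3L, byrow = TRUE)
    rowSums(D * normals)
  }
  pt <- proj(template); pr <- proj(reference)
  r <- if (stats::var(pt) == 0 || stats::var(pr) == 0) NA_real_ else
    stats::cor(pt, pr)
  list(mae = mae, r_inout = r)
}
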