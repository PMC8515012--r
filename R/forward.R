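# Linear forward models from predictor spaces to single-trial ratings.
# Ridge with a dedicated L2 penalty per predictor subspace, tuned in nested
# cross-validation over consecutive trial blocks by maximizing Kendall's tau
# on held-out validation blocks.

#' Construct a predictor space
#'
#' A named trials x channels matrix with a partition of its columns into
#' named subspaces; joint models concatenate subspaces and give each its own
#' ridge penalty.
#'
#' @param name identifier.
#' @param values numeric matrix (trials x channels), no missing values.
#' @param subspaces named list of integer column index vectors that
#'   partition `1:ncol(values)`; default: one subspace holding everything.
#' @return object of class `predictor_space`.
#' @export
predictor_space <- function(name, values,
                            subspaces = stats::setNames(list(seq_len(ncol(values))), name)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("predictor space contains missing values")
  all_idx <- sort(unlist(subspaces, use.names = FALSE))
  if (!identical(all_idx, seq_len(ncol(values))))
    stop("subspaces must partition 1:", ncol(values))
  structure(list(name = name, values = values, subspaces = subspaces),
            class = "predictor_space")
}

#' Concatenate predictor spaces into a joint space
#'
#' @param ... `predictor_space` objects over the same trials.
#' @param name name for the joint space.
#' @return a `predictor_space` whose subspaces are the inputs' subspaces.
#' @export
joint_space <- function(..., name = NULL) {
  spaces <- list(...)
  n <- nrow(spaces[[1L]]$values)
  stopifnot(all(vapply(spaces, function(s) nrow(s$values), 0L) == n))
  vals <- do.call(cbind, lapply(spaces, `[[`, "values"))
  offs <- cumsum(c(0L, vapply(spaces, function(s) ncol(s$values), 0L)))
  subs <- list()
  for (i in seq_along(spaces))
    for (nm in names(spaces[[i]]$subspaces))
      subs[[nm]] <- spaces[[i]]$subspaces[[nm]] + offs[i]
  if (is.null(name)) name <- paste(vapply(spaces, `[[`, "", "name"),
                                   collapse = "+")
  predictor_space(name, vals, subs)
}

#' Closed-form ridge solution with per-subspace penalties
#'
#' Solves B = (X'X + R)^-1 X'y with R diagonal, constant within each
#' subspace, via a symmetric (Cholesky) solve. X is expected standardized
#' and y centered by the caller (training statistics); no intercept is fit.
#'
#' @param X n x M numeric matrix.
#' @param y length-n numeric response.
#' @param lambdas one non-negative penalty per subspace.
#' @param slices list of column index vectors, one per subspace.
#' @return length-M weight vector.
#' @export
ridge_solve <- function(X, y, lambdas, slices = list(seq_len(ncol(X)))) {
  stopifnot(length(lambdas) == length(slices), all(lambdas >= 0))
  M <- ncol(X)
  r <- numeric(M)
  for (s in seq_along(slices)) r[slices[[s]]] <- lambdas[s]
  G <- crossprod(X)
  diag(G) <- diag(G) + r
  ch <- tryCatch(chol(G), error = function(e)
    stop("X'X + R is singular or not positive definite; ",
         "use lambda > 0 for rank-deficient predictors"))
  # chol can succeed numerically on a singular Gram matrix; reject that
  # case when it cannot be blamed on a positive penalty
  if (any(lambdas == 0) && min(diag(ch))^2 < 1e-10 * max(diag(G)))
    stop("X'X + R is numerically singular; use lambda > 0 for ",
         "rank-deficient predictors")
  drop(backsolve(ch, backsolve(ch, crossprod(X, y), transpose = TRUE)))
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau computed from exact concordant/discordant pair counts.
#' Returns `NA` (the undefined code) when either argument has zero variance.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return tau-b in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
kendall_tau <- function(a, b) {
  n <- length(a)
  if (n < 2L || length(b) != n) stop("need two equal-length vectors, n >= 2")
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) return(NA_real_)
  ia <- upper.tri(matrix(0, n, n))
  da <- sign(outer(a, a, "-"))[ia]
  db <- sign(outer(b, b, "-"))[ia]
  S <- sum(da * db)
  n0 <- n * (n - 1) / 2
  t1 <- sum(da == 0)
  t2 <- sum(db == 0)
  S / sqrt((n0 - t1) * (n0 - t2))
}

#' Consecutive-block cross-validation layout
#'
#' Partitions trials into consecutive blocks of `fold_len`; each block serves
#' once as the outer test set, and within each outer fold each remaining
#' block serves once as the inner validation set.
#'
#' @param n_trials total trials (must be divisible by `fold_len`).
#' @param fold_len block length (default 200).
#' @return list with `blocks` (list of index vectors), `n_outer`, `n_inner`.
#' @export
cv_layout <- function(n_trials, fold_len = 200L) {
  if (n_trials %% fold_len != 0L)
    stop("n_trials (", n_trials, ") not divisible by fold_len (", fold_len, ")")
  n_blocks <- n_trials %/% fold_len
  if (n_blocks < 3L) stop("need at least 3 blocks; got ", n_blocks)
  blocks <- split(seq_len(n_trials), rep(seq_len(n_blocks), each = fold_len))
  list(blocks = unname(blocks), n_outer = n_blocks, n_inner = n_blocks - 1L)
}

std_stats <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(center = m, scale = s)
}
std_apply <- function(X, st) sweep(sweep(X, 2L, st$center), 2L, st$scale, "/")

# Deterministic per-subspace penalty search on the log2 scale: a coarse
# sweep over exponents in [-30, 30], coordinate-wise, then local refinement.
# Ties in validation tau are broken toward the smallest penalty. The budget
# caps the number of ridge evaluations (the stochastic optimizer the field
# sometimes uses is replaced by this reproducible search).
default_search <- function() list(coarse_step = 6, refine_steps = c(3, 1.5),
                                  n_pass = 2L, max_evals = 200L,
                                  init_exp = 17, bounds = c(-30, 30))

tune_lambdas <- function(Xtr, ytr, Xval, yval, slices, search = default_search()) {
  n_sub <- length(slices)
  exps <- rep(search$init_exp, n_sub)
  evals <- 0L
  score <- function(e) {
    evals <<- evals + 1L
    B <- ridge_solve(Xtr, ytr, 2^e, slices)
    kendall_tau(drop(Xval %*% B), yval)
  }
  best_tau <- score(exps)
  if (is.na(best_tau)) best_tau <- -Inf
  sweep_coord <- function(cands) {
    for (s in seq_len(n_sub)) {
      cand <- sort(unique(pmin(pmax(cands, search$bounds[1]), search$bounds[2])))
      for (e in cand) {
        if (evals >= search$max_evals) return(invisible(NULL))
        if (e == exps[s]) next
        trial <- exps; trial[s] <- e
        tau <- score(trial)
        if (is.na(tau)) next
        if (tau > best_tau + 1e-12 ||
            (abs(tau - best_tau) <= 1e-12 && e < exps[s])) {
          best_tau <<- max(tau, best_tau); exps <<- trial
        }
      }
    }
  }
  for (p in seq_len(search$n_pass))
    sweep_coord(seq(search$bounds[1], search$bounds[2], by = search$coarse_step))
  for (st in search$refine_steps)
    sweep_coord(c(exps - st, exps + st))
  list(exponents = exps, lambdas = 2^exps, tau = best_tau, evals = evals)
}

# Fit one outer fold: tune per-subspace penalties on inner folds over the
# development blocks, take the median penalty, retrain on the full
# development set, and predict the untouched test block.
fit_fold <- function(X, y, dev_blocks, test_idx, slices, search) {
  inner <- lapply(seq_along(dev_blocks), function(v) {
    val_idx <- dev_blocks[[v]]
    tr_idx <- unlist(dev_blocks[-v], use.names = FALSE)
    st <- std_stats(X[tr_idx, , drop = FALSE])
    Xtr <- std_apply(X[tr_idx, , drop = FALSE], st)
    Xval <- std_apply(X[val_idx, , drop = FALSE], st)
    tune_lambdas(Xtr, y[tr_idx] - mean(y[tr_idx]), Xval, y[val_idx],
                 slices, search)
  })
  lam_mat <- do.call(rbind, lapply(inner, `[[`, "lambdas"))
  lambdas <- apply(lam_mat, 2L, stats::median)
  dev_idx <- unlist(dev_blocks, use.names = FALSE)
  st <- std_stats(X[dev_idx, , drop = FALSE])
  y_center <- mean(y[dev_idx])
  B <- ridge_solve(std_apply(X[dev_idx, , drop = FALSE], st),
                   y[dev_idx] - y_center, lambdas, slices)
  pred <- drop(std_apply(X[test_idx, , drop = FALSE], st) %*% B) + y_center
  list(weights = B, lambdas = lambdas, test_idx = test_idx,
       predictions = pred, x_stats = st, y_center = y_center,
       inner_lambdas = lam_mat,
       inner_taus = vapply(inner, `[[`, 0, "tau"))
}

#' Nested cross-validated forward model
#'
#' Consecutive blocks of `fold_len` trials form the outer folds; within each
#' outer fold every remaining block serves once as an inner validation set
#' on which the per-subspace ridge penalties are tuned to maximize Kendall's
#' tau (search initialized at 2^17 within [2^-30, 2^30]). The median penalty
#' across inner folds is used to retrain on the full development set, and
#' predictions are emitted for the untouched test block, so every trial
#' receives exactly one out-of-fold prediction.
#'
#' @param space a `predictor_space`.
#' @param ratings numeric response vector (one per trial), non-constant.
#' @param fold_len trials per block (default 200).
#' @param search search settings, see source of `default_search()`.
#' @return object of class `forward_fit`: per-fold weights, penalties and
#'   test predictions, plus the assembled out-of-fold prediction vector.
#' @export
nested_cv_fit <- function(space, ratings, fold_len = 200L,
                          search = default_search()) {
  stopifnot(inherits(space, "predictor_space"))
  X <- space$values
  n <- nrow(X)
  if (length(ratings) != n) stop("ratings length != number of trials")
  if (length(unique(ratings)) == 1L) stop("ratings are constant")
  lay <- cv_layout(n, fold_len)
  slices <- space$subspaces
  folds <- lapply(seq_len(lay$n_outer), function(b) {
    fit_fold(X, ratings, lay$blocks[-b], lay$blocks[[b]], slices, search)
  })
  pred <- numeric(n)
  for (f in folds) pred[f$test_idx] <- f$predictions
  tau_test <- vapply(folds, function(f)
    kendall_tau(f$predictions, ratings[f$test_idx]), numeric(1))
  structure(list(space_name = space$name, subspaces = slices,
                 fold_len = fold_len, folds = folds,
                 predictions = pred, ratings = ratings,
                 tau_test = tau_test),
            class = "forward_fit")
}

#' @export
print.forward_fit <- function(x, ...) {
  cat("Forward model fit:", x$space_name, "\n")
  cat("  outer folds:", length(x$folds), " (", x$fold_len, "trials each)\n")
  cat("  median out-of-fold tau:", round(stats::median(x$tau_test), 3), "\n")
  invisible(x)
}

#' Shape receptive field of a forward fit
#'
#' Fold-averaged forward weights over shape components, projected through
#' the orthonormal residual basis into vertex space.
#'
#' @param fit a `forward_fit` over shape components.
#' @param model optional `gmf_model` for the vertex-space projection.
#' @return object of class `srf`: `weights_components` and (when a model is
#'   supplied) `weights_vertices = U %*% weights_components`.
#' @export
srf_from_fit <- function(fit, model = NULL) {
  W <- do.call(cbind, lapply(fit$folds, `[[`, "weights"))
  w <- rowMeans(W)
  out <- list(weights_components = w, per_fold = W)
  if (!is.null(model)) out$weights_vertices <- drop(model$U_shape %*% w)
  structure(out, class = "srf")
}

#' Re-predict a forward model's predictions from shape features
#'
#' For each outer fold of an embedding-based fit, the fold model's
#' predictions are regressed on the shape feature space (penalty tuned on
#' the fold's inner blocks), giving simulated predictions and simulated
#' shape weights. Reports, per fold, the correlation of simulated with
#' original test predictions and (when a shape fit is supplied) of simulated
#' with original shape weights.
#'
#' @param fit_embed `forward_fit` on the embedding space.
#' @param space_embed,space_shape the embedding and shape predictor spaces
#'   (identical trials).
#' @param fit_shape optional `forward_fit` on the shape space for weight
#'   comparison.
#' @param search penalty search settings.
#' @return list with `B_SN` (M_shape x folds matrix), `yhat`, `yhathat`
#'   (out-of-fold original and simulated predictions), `pred_corr`,
#'   `srf_corr` (per-fold).
#' @export
srf_and_repredict <- function(fit_embed, space_embed, space_shape,
                              fit_shape = NULL, search = default_search()) {
  if (nrow(space_embed$values) != nrow(space_shape$values))
    stop("embedding and shape spaces cover different trials")
  n <- nrow(space_embed$values)
  lay <- cv_layout(n, fit_embed$fold_len)
  Xs <- space_shape$values
  nf <- length(fit_embed$folds)
  pred_corr <- srf_corr <- numeric(nf)
  B_SN <- matrix(NA_real_, ncol(Xs), nf)
  yhat <- yhathat <- numeric(n)
  for (b in seq_len(nf)) {
    f <- fit_embed$folds[[b]]
    # fold model predictions for every trial, using the fold's training stats
    yh <- drop(std_apply(space_embed$values, f$x_stats) %*% f$weights) +
      f$y_center
    ff <- fit_fold(Xs, yh, lay$blocks[-b], lay$blocks[[b]],
                   space_shape$subspaces, search)
    B_SN[, b] <- ff$weights
    yhat[f$test_idx] <- yh[f$test_idx]
    yhathat[f$test_idx] <- ff$predictions
    pred_corr[b] <- stats::cor(yh[f$test_idx], ff$predictions)
    if (!is.null(fit_shape))
      srf_corr[b] <- stats::cor(fit_shape$folds[[b]]$weights, ff$weights)
  }
  list(B_SN = B_SN, yhat = yhat, yhathat = yhathat,
       pred_corr = pred_corr,
       srf_corr = if (is.null(fit_shape)) NULL else srf_corr)
}

#' Decode shape components from an embedding and map the error to vertices
#'
#' Ridge decoders predict each shape component from all embedding channels;
#' penalties are tuned per component on a tuning split (log2-spaced grid,
#' minimum tuning mean squared error), predictions for the test split are
#' projected into vertex space, and the per-vertex Euclidean error between
#' predicted and true coordinates is averaged over test faces.
#'
#' @param space `predictor_space` of embedding activations (stimuli x
#'   channels).
#' @param components true shape components (stimuli x K).
#' @param model `gmf_model` providing the vertex projection.
#' @param split train/tune/test fractions summing to 1.
#' @param seed split seed.
#' @param lambda_exponents log2 penalty grid.
#' @return list with `mae_vertex` (length-V map), `pred_components`,
#'   `test_idx`, `lambda` per component.
#' @export
decode_shape <- function(space, components, model,
                         split = c(0.8, 0.1, 0.1), seed = 1L,
                         lambda_exponents = seq(-30, 30, by = 3)) {
  X <- space$values
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 stimuli")
  if (abs(sum(split) - 1) > 1e-8 || any(split <= 0))
    stop("split fractions must be positive and sum to 1")
  set.seed(seed)
  idx <- sample(n)
  n_tr <- floor(split[1] * n); n_tu <- floor(split[2] * n)
  if (n_tr < 2L || n_tu < 1L || n - n_tr - n_tu < 1L)
    stop("degenerate split sizes for n = ", n)
  tr <- idx[seq_len(n_tr)]
  tu <- idx[n_tr + seq_len(n_tu)]
  te <- idx[(n_tr + n_tu + 1L):n]

  st <- std_stats(X[tr, , drop = FALSE])
  Xtr <- std_apply(X[tr, , drop = FALSE], st)
  Xtu <- std_apply(X[tu, , drop = FALSE], st)
  Xte <- std_apply(X[te, , drop = FALSE], st)
  Y <- as.matrix(components)
  yc <- colMeans(Y[tr, , drop = FALSE])
  Ytr <- sweep(Y[tr, , drop = FALSE], 2L, yc)

  G <- crossprod(Xtr)
  XtY <- crossprod(Xtr, Ytr)
  K <- ncol(Y)
  best_mse <- rep(Inf, K)
  best_B <- matrix(0, ncol(X), K)
  best_lam <- numeric(K)
  for (e in lambda_exponents) {
    Ge <- G; diag(Ge) <- diag(Ge) + 2^e
    B <- tryCatch(solve(Ge, XtY), error = function(err) NULL)
    if (is.null(B)) next
    P <- Xtu %*% B
    mse <- colMeans((sweep(Y[tu, , drop = FALSE], 2L, yc) - P)^2)
    upd <- mse < best_mse - 1e-15
    best_mse[upd] <- mse[upd]
    best_B[, upd] <- B[, upd]
    best_lam[upd] <- 2^e
  }
  pred <- sweep(Xte %*% best_B, 2L, yc, "+")

  to_vertex <- function(C) C %*% (t(model$U_shape) * model$scale_shape)
  Dv <- to_vertex(pred) - to_vertex(Y[te, , drop = FALSE])
  V <- model$n_vertices
  err2 <- Dv^2
  # per-face per-vertex Euclidean norm over xyz, then mean over faces
  vx <- err2[, seq(1L, 3L * V, by = 3L), drop = FALSE] +
    err2[, seq(2L, 3L * V, by = 3L), drop = FALSE] +
    err2[, seq(3L, 3L * V, by = 3L), drop = FALSE]
  list(mae_vertex = colMeans(sqrt(vx)), pred_components = pred,
       test_idx = te, lambda = best_lam)
}

#' Distance features relative to reference points
#'
#' For each reference point in channel space, emits a scalar Euclidean
#' distance subspace and a channel-wise absolute difference subspace (whose
#' ridge weighting yields a weighted Euclidean distance).
#'
#' @param space a `predictor_space`.
#' @param refs matrix of reference points (one per row, same channels).
#' @return a `predictor_space` with `2 * nrow(refs)` subspaces.
#' @export
build_distance_features <- function(space, refs) {
  refs <- rbind(refs)
  if (ncol(refs) != ncol(space$values))
    stop("reference points have ", ncol(refs), " channels, space has ",
         ncol(space$values))
  blocks <- list(); subs <- list(); off <- 0L
  for (j in seq_len(nrow(refs))) {
    D <- sweep(space$values, 2L, refs[j, ])
    scal <- sqrt(rowSums(D^2))
    blocks[[length(blocks) + 1L]] <- unname(cbind(scal, abs(D)))
    subs[[paste0("ref", j, "_dist")]] <- off + 1L
    subs[[paste0("ref", j, "_chan")]] <- off + 1L + seq_len(ncol(D))
    off <- off + 1L + ncol(D)
  }
  predictor_space(paste0(space$name, "_dist"), do.call(cbind, blocks), subs)
}
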