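# minimal pseudoinverse helper (SVD-based), independent of the package path
MASS_free_pinv <- function(X) {
  s <- svd(X)
  s$v %*% (t(s$u) / s$d)
}

test_that("ridge_solve matches closed forms and oracles", {
  # hand-evaluated example: X = [[1],[2]], y = (1,2), lambda = 2 -> 5/7
  B <- ridge_solve(matrix(c(1, 2)), c(1, 2), 2)
  expect_equal(B, 5 / 7, tolerance = 1e-12)

  # orthonormal X at lambda 0: B = X'y
  Q <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  y <- rnorm(10)
  expect_equal(ridge_solve(Q, y, 0), drop(crossprod(Q, y)), tolerance = 1e-8)

  # per-subspace penalties match the explicit-inverse oracle
  set.seed(3)
  X <- matrix(rnorm(60), 12, 5)
  slices <- list(1:2, 3:5)
  lam <- c(0.7, 13)
  expect_equal(ridge_solve(X, y <- rnorm(12), lam, slices),
               drop(oracle_ridge(X, y, c(0.7, 0.7, 13, 13, 13))),
               tolerance = 1e-8)

  # lambda 0 on full-rank X matches the pseudoinverse
  expect_equal(ridge_solve(X, y, 0, list(1:5)),
               drop(MASS_free_pinv(X) %*% y), tolerance = 1e-8)

  # shrinkage limit
  expect_lt(sqrt(sum(ridge_solve(X, y, 2^30, list(1:5))^2)),
            1e-6 * sqrt(sum(crossprod(X, y)^2)))

  # rank-deficient X at lambda 0 errors with advice
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(ridge_solve(Xr, y, 0, list(1:3)), "lambda > 0")
})

test_that("kendall_tau is tau-b and matches pair enumeration", {
  a <- c(1, 2, 3, 4)
  expect_equal(kendall_tau(a, a), 1)
  expect_equal(kendall_tau(a, rev(a)), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 3), c(1, 3, 2, 2)),
               oracle_kendall(c(1, 2, 3, 3), c(1, 3, 2, 2)))
  set.seed(8)
  for (r in 1:20) {
    x <- sample(1:6, 30, replace = TRUE)
    y <- sample(1:6, 30, replace = TRUE)
    expect_equal(kendall_tau(x, y), oracle_kendall(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(x, y), kendall_tau(y, x))
  }
  expect_true(is.na(kendall_tau(rep(1, 5), 1:5)))
})

test_that("cv layout produces consecutive blocks with correct counts", {
  lay <- cv_layout(1800L, 200L)
  expect_equal(lay$n_outer, 9L)
  expect_equal(lay$n_inner, 8L)
  expect_equal(lay$blocks[[1]], 1:200)
  expect_equal(lay$blocks[[9]], 1601:1800)
  expect_error(cv_layout(1800L, 700L), "divisible")
  expect_error(cv_layout(400L, 200L), "3 blocks")
})

test_that("nested CV predicts a noiseless linear observer well", {
  # default synthetic scale (1800 trials, 200-blocks); ratings binned to 6
  # levels cap attainable tau-b near sqrt(5/6) ~ 0.913
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0, trials = 1800L)
  sp <- predictor_space("shape",
                        ts$stimuli$components[ts$chosen, , drop = FALSE])
  fit <- nested_cv_fit(sp, ts$session$rating, fold_len = 200L)
  expect_equal(length(fit$folds), 9L)
  # out-of-fold predictions cover every trial exactly once
  covered <- sort(unlist(lapply(fit$folds, `[[`, "test_idx")))
  expect_equal(covered, 1:1800)
  expect_gt(stats::median(fit$tau_test), 0.9)
  expect_true(all(unlist(lapply(fit$folds, `[[`, "lambdas")) >= 2^-30))
  expect_true(all(unlist(lapply(fit$folds, `[[`, "lambdas")) <= 2^30))
})

test_that("no leakage: test-block labels cannot affect test predictions", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0.5, trials = 80L)
  sp <- predictor_space("shape",
                        ts$stimuli$components[ts$chosen, , drop = FALSE])
  fit <- nested_cv_fit(sp, ts$session$rating, fold_len = 20L)
  y2 <- ts$session$rating
  y2[fit$folds[[2]]$test_idx] <- sample(y2[fit$folds[[2]]$test_idx])
  fit2 <- nested_cv_fit(sp, y2, fold_len = 20L)
  expect_equal(fit2$folds[[2]]$predictions, fit$folds[[2]]$predictions,
               tolerance = 1e-12)
})

test_that("shuffled ratings stay below the permutation threshold", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0.3, trials = 80L)
  sp <- predictor_space("shape",
                        ts$stimuli$components[ts$chosen, , drop = FALSE])
  eval_mi <- function(y) {
    f <- nested_cv_fit(sp, y, fold_len = 20L)
    mutual_information_mm(bin_equipopulated(f$predictions),
                          bin_equipopulated(y))
  }
  set.seed(99)
  y_shuf <- sample(ts$session$rating)
  thr <- permutation_null(eval_mi, y_shuf, n_perm = 20L, seed = 1)
  # reduced-profile guard only; full calibration lives in the acceptance suite
  expect_lt(eval_mi(y_shuf), as.numeric(thr) + 0.05)
})

test_that("joint space with a shape-faithful embedding does not beat shape alone", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0.5)
  sp_shape <- predictor_space("shape",
                              ts$stimuli$components[ts$chosen, , drop = FALSE])
  emb <- generate_embedding(embedding_spec("emb", dim = 16L, seed = 2),
                            ts$stimuli, w$model)
  sp_emb <- predictor_space("emb", emb$values[ts$chosen, , drop = FALSE])
  fit_s <- nested_cv_fit(sp_shape, ts$session$rating, fold_len = 20L)
  fit_j <- nested_cv_fit(joint_space(sp_shape, sp_emb),
                         ts$session$rating, fold_len = 20L)
  expect_equal(length(fit_j$folds[[1]]$lambdas), 2L)
  expect_lte(stats::median(fit_j$tau_test),
             stats::median(fit_s$tau_test) + 0.05)
})

test_that("SRF recovery from a linear observer at moderate noise", {
  w <- tiny_world()
  cors <- sapply(1:10, function(s) {
    set.seed(1000 + s)
    wts <- runif(w$model$K_shape, 0.2, 1)
    ts <- tiny_session(w, obs_seed = 2000 + s, stim_seed = 3000 + s,
                       type = "linear", weights = wts, trials = 120L)
    sig <- stats::sd(facefwd:::observer_score(ts$observer,
                                              ts$stimuli$components))
    ts <- tiny_session(w, obs_seed = 2000 + s, stim_seed = 3000 + s,
                       type = "linear", weights = wts, trials = 120L,
                       noise_sd = 0.5 * sig)
    sp <- predictor_space("shape",
                          ts$stimuli$components[ts$chosen, , drop = FALSE])
    fit <- nested_cv_fit(sp, ts$session$rating, fold_len = 20L)
    cor(srf_from_fit(fit)$weights_components, wts)
  })
  expect_gte(stats::median(cors), 0.9)
})

test_that("SRF vertex form is the basis image of the component form", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear")
  sp <- predictor_space("shape",
                        ts$stimuli$components[ts$chosen, , drop = FALSE])
  fit <- nested_cv_fit(sp, ts$session$rating, fold_len = 20L)
  srf <- srf_from_fit(fit, w$model)
  expect_equal(srf$weights_vertices,
               drop(w$model$U_shape %*% srf$weights_components),
               tolerance = 1e-8)
})

test_that("re-prediction closes under linear maps and on the shape space itself", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0.3)
  Xs <- ts$stimuli$components[ts$chosen, , drop = FALSE]
  sp_shape <- predictor_space("shape", Xs)
  # exact linear image of the shape features
  set.seed(5)
  M <- qr.Q(qr(matrix(rnorm(8 * 8), 8, 8)))
  sp_lin <- predictor_space("lin", Xs %*% M)
  fit_lin <- nested_cv_fit(sp_lin, ts$session$rating, fold_len = 20L)
  fit_shape <- nested_cv_fit(sp_shape, ts$session$rating, fold_len = 20L)
  rp <- srf_and_repredict(fit_lin, sp_lin, sp_shape, fit_shape = fit_shape)
  expect_gt(min(rp$pred_corr), 0.999)

  # self re-prediction returns the original weights
  rp_self <- srf_and_repredict(fit_shape, sp_shape, sp_shape,
                               fit_shape = fit_shape)
  for (b in seq_along(fit_shape$folds))
    expect_equal(rp_self$B_SN[, b], fit_shape$folds[[b]]$weights,
                 tolerance = 1e-6)

  # pure-noise embedding: simulated predictions near-uncorrelated
  set.seed(6)
  sp_noise <- predictor_space("noise", matrix(rnorm(180 * 8), 180, 8))
  fit_noise <- nested_cv_fit(sp_noise, ts$session$rating, fold_len = 20L)
  rp_noise <- srf_and_repredict(fit_noise, sp_noise, sp_shape)
  expect_lt(abs(stats::median(rp_noise$pred_corr)), 0.5)
})

test_that("decoding recovers components through a faithful embedding", {
  w <- tiny_world()
  stim <- generate_stimulus_set(w$model, 300L, factors = w$factors, seed = 6)
  emb <- generate_embedding(embedding_spec("e", dim = 16L, seed = 7),
                            stim, w$model)
  dec <- decode_shape(emb, stim$components, w$model, seed = 8)
  expect_lt(max(dec$mae_vertex), 1e-6)

  # an embedding blind to component 1 keeps at least its vertex contribution
  blind <- stim
  blind$components <- stim$components
  blind$components[, 1] <- 0
  emb_b <- generate_embedding(embedding_spec("b", dim = 16L, seed = 7),
                              blind, w$model)
  dec_b <- decode_shape(emb_b, stim$components, w$model, seed = 8)
  # lower bound: expected |c_1| times the vertex magnitude of basis column 1
  u1 <- matrix(w$model$U_shape[, 1] * w$model$scale_shape[1],
               ncol = 3, byrow = TRUE)
  expect_gt(mean(dec_b$mae_vertex), 0.5 * mean(sqrt(rowSums(u1^2))))

  # shared blind spots give correlated error maps
  emb_b2 <- generate_embedding(embedding_spec("b2", dim = 24L, seed = 17),
                               blind, w$model)
  dec_b2 <- decode_shape(emb_b2, stim$components, w$model, seed = 8)
  expect_gt(cor(dec_b$mae_vertex, dec_b2$mae_vertex), 0.9)

  expect_error(decode_shape(emb, stim$components, w$model,
                            split = c(0.5, 0.4, 0.1, 0)), "split")
})

test_that("distance features reproduce Euclidean geometry and weighted fits", {
  sp <- predictor_space("e", matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE))
  df <- build_distance_features(sp, matrix(c(0, 0), 1))
  expect_equal(df$values[2, 1], 0)       # stimulus equal to reference
  expect_equal(df$values[1, 1], 5)       # (3,4) vs origin
  expect_equal(length(df$subspaces), 2L)

  # ridge on channel-wise features matches a direct weighted-distance fit
  set.seed(9)
  X <- matrix(rnorm(100), 50, 2)
  ref <- c(0.5, -0.2)
  wtrue <- c(2, 0.7)
  y <- drop(abs(sweep(X, 2, ref)) %*% wtrue)
  dfx <- build_distance_features(predictor_space("x", X), matrix(ref, 1))
  A <- abs(sweep(X, 2, ref))
  oracle_w <- drop(oracle_ridge(scale(A), y - mean(y), rep(1e-8, 2)))
  Bfit <- ridge_solve(scale(A), y - mean(y), 1e-8, list(1:2))
  expect_equal(Bfit, oracle_w, tolerance = 1e-6)
  expect_error(build_distance_features(sp, matrix(0, 1, 3)), "channels")
})
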