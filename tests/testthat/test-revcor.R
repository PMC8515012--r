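test_that("choose_faces picks the maximum with documented tie-breaking", {
  arrays <- rbind(1:6, 7:12)
  preds <- c(0, 3, 1, 0, 0, 0, rep(2, 6))
  ch <- suppressMessages(choose_faces(preds, arrays))
  expect_equal(ch$chosen_stimulus[1], 2L)
  expect_equal(ch$chosen_col[2], 1L)          # all-equal: lowest index
  expect_equal(attr(ch, "n_ties"), 1L)
  expect_error(choose_faces(c(preds[-12], NA), arrays), "trial")
})

test_that("a perfect model reproduces a noiseless observer's choices", {
  w <- tiny_world()
  ts <- tiny_session(w, type = "linear", noise_sd = 0, trials = 100L)
  scores <- facefwd:::observer_score(ts$observer, ts$stimuli$components)
  ch <- choose_faces(scores, attr(ts$session, "arrays"))
  expect_gte(mean(ch$chosen_stimulus == attr(ts$session, "chosen_stimulus")),
             0.99)
})

test_that("mass-univariate fit matches the two-parameter closed form", {
  r <- rep(1:6, each = 10)
  Fm <- cbind(2 + 3 * r, 5 - 0.5 * r)
  fit <- mass_univariate_fit(Fm, r)
  expect_equal(fit$b0, c(2, 5), tolerance = 1e-10)
  expect_equal(fit$b1, c(3, -0.5), tolerance = 1e-10)

  # OLS path vs per-coordinate normal-equations oracle
  set.seed(4)
  Fm <- matrix(rnorm(60 * 5), 60, 5)
  r <- sample(1:6, 60, replace = TRUE)
  fit <- mass_univariate_fit(Fm, r)
  X <- cbind(1, r)
  oracle <- oracle_normal_equations(X, Fm)
  expect_equal(fit$b0, unname(oracle[1, ]), tolerance = 1e-10)
  expect_equal(fit$b1, unname(oracle[2, ]), tolerance = 1e-10)

  # feature independent of rating: slope within 3 standard errors
  set.seed(5)
  n <- 10000L
  f1 <- rnorm(n); rr <- sample(1:6, n, replace = TRUE)
  fit0 <- mass_univariate_fit(cbind(f1), rr)
  se <- summary(lm(f1 ~ rr))$coefficients[2, 2]
  expect_lt(abs(fit0$b1), 3 * se)

  expect_error(mass_univariate_fit(Fm, rep(3, 60)), "constant")
  expect_error(mass_univariate_fit(Fm[1:2, ], r[1:2]), "3 trials")
})

test_that("robust fit agrees with OLS on clean data and resists outliers", {
  set.seed(6)
  r <- rep(1:6, each = 20)
  Fm <- cbind(1 + 2 * r + rnorm(120, sd = 0.1))
  ols <- mass_univariate_fit(Fm, r)
  rob <- mass_univariate_fit(Fm, r, method = "robust")
  expect_equal(rob$b1, ols$b1, tolerance = 0.05)
  Fo <- Fm; Fo[1:3] <- 100
  rob_o <- mass_univariate_fit(Fo, r, method = "robust")
  ols_o <- mass_univariate_fit(Fo, r)
  expect_lt(abs(rob_o$b1 - 2), abs(ols_o$b1 - 2))
})

test_that("amplification tuning: linear responders are monotone, flat slopes flat", {
  rc <- structure(list(b0 = c(1, 2), b1 = c(0.5, -0.2)), class = "revcor_fit")
  lin <- function(face) sum(face * c(2, 1))
  tc <- amplification_tuning(rc, lin, amp_grid = seq(0, 50, 0.5))
  expect_true(all(diff(tc$responses) >= -1e-12))
  expect_equal(tc$peak_amp, 50)

  rc0 <- structure(list(b0 = c(1, 2), b1 = c(0, 0)), class = "revcor_fit")
  tc0 <- suppressMessages(amplification_tuning(rc0, lin))
  expect_equal(tc0$peak_amp, 0)
  expect_error(amplification_tuning(rc, lin, amp_grid = numeric(0)), "empty")
})

test_that("distance responders peak where a dense grid says they should", {
  set.seed(7)
  b0 <- rnorm(10); b1 <- rnorm(10, sd = 0.2); target <- b0 + 7.3 * b1
  rc <- structure(list(b0 = b0, b1 = b1), class = "revcor_fit")
  resp <- function(face) -sum((face - target)^2)
  tc <- amplification_tuning(rc, resp, amp_grid = seq(0, 50, 0.5))
  dense <- seq(0, 50, 0.01)
  oracle_peak <- dense[which.max(sapply(dense, function(a)
    resp(b0 + a * b1)))]
  expect_lt(abs(tc$peak_amp - oracle_peak), 0.5)
})

test_that("template metrics: identity, degeneracy and arithmetic oracle", {
  w <- tiny_world()
  proto <- gmf_prototype(w$factors, w$model)
  tpl <- synthesize_vertices(rnorm(8), w$factors, w$model)
  m_id <- template_metrics(tpl, tpl, proto)
  expect_equal(m_id$mae, 0)
  expect_equal(m_id$r_inout, 1)

  m_deg <- template_metrics(proto, tpl, proto)
  expect_true(is.na(m_deg$r_inout))

  ref <- synthesize_vertices(rnorm(8), w$factors, w$model)
  m <- template_metrics(tpl, ref, proto)
  expect_equal(m$mae, mean(abs(tpl - ref)), tolerance = 1e-12)
})

test_that("reverse correlation recovers a noiseless observer's template", {
  w <- tiny_world()
  cors <- sapply(1:10, function(s) {
    ts <- tiny_session(w, obs_seed = 5000 + s, stim_seed = 6000 + s,
                       type = "distance", noise_sd = 0, trials = 300L)
    rc <- mass_univariate_fit(ts$chosen_components, ts$session$rating)
    cor(rc$b1, ts$observer$template_components)
  })
  expect_gte(stats::median(cors), 0.95)
})

test_that("slopes are proportional to forward weights on whitened data", {
  # with z-scored features and responses, the mass-univariate slope equals
  # the correlation, which for an orthonormal design equals the forward
  # weight up to a common scale
  set.seed(8)
  X <- matrix(rnorm(500 * 4), 500, 4)
  X <- scale(X %*% solve(chol(stats::cov(X))))  # exactly whitened
  b <- c(1, -0.5, 0.3, 0)
  y <- drop(scale(X %*% b))
  rc <- mass_univariate_fit(X, y)
  fw <- ridge_solve(scale(X), y - mean(y), 1e-10, list(1:4))
  expect_gt(abs(cor(rc$b1, fw)), 0.999)
})

test_that("shape-faithful embeddings yield more human templates than noise", {
  w <- tiny_world()
  for (s in 1:3) {
    ts <- tiny_session(w, obs_seed = 7000 + s, stim_seed = 8000 + s,
                       type = "distance", noise_sd = 0, trials = 300L)
    rc_obs <- mass_univariate_fit(ts$chosen_components, ts$session$rating)
    # model behavior: predicted ratings from each embedding's forward fit
    mk_pred <- function(spec) {
      sp <- generate_embedding(spec, ts$stimuli, w$model)
      Xc <- sp$values[ts$chosen, , drop = FALSE]
      B <- ridge_solve(scale(Xc), ts$session$rating -
                         mean(ts$session$rating), 1, list(seq_len(ncol(Xc))))
      drop(scale(Xc) %*% B) + mean(ts$session$rating)
    }
    p_faithful <- mk_pred(embedding_spec("f", 16L, shape_fidelity = 0.95,
                                         noise_sd = 0.05, seed = s))
    p_noise <- mk_pred(embedding_spec("n", 16L, shape_fidelity = 0,
                                      texture_fidelity = 0, noise_sd = 1,
                                      seed = s))
    rc_f <- mass_univariate_fit(ts$chosen_components, p_faithful)
    rc_n <- mass_univariate_fit(ts$chosen_components, p_noise)
    d_f <- sum((rc_f$b1 / max(abs(rc_f$b1)) -
                  rc_obs$b1 / max(abs(rc_obs$b1)))^2)
    d_n <- sum((rc_n$b1 / max(abs(rc_n$b1)) -
                  rc_obs$b1 / max(abs(rc_obs$b1)))^2)
    expect_lt(d_f, d_n)
  }
})
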