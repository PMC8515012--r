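test_that("faithfulness classification is the strict elementwise rule", {
  expect_true(classify_faithful(1, 2, 1))      # recon = truth, chance off
  expect_false(classify_faithful(2, 2, 1))     # recon = chance: strict
  set.seed(1)
  r <- rnorm(20); ch <- rnorm(20); tr <- rnorm(20)
  expect_equal(classify_faithful(r, ch, tr), abs(ch - tr) > abs(r - tr))
  expect_error(classify_faithful(c(1, NA), c(1, 2), c(0, 0)), "NaN/NA")
})

test_that("NMF reconstructs low-rank non-negative structure", {
  set.seed(2)
  W0 <- matrix(runif(30 * 2), 30, 2)
  H0 <- matrix(runif(2 * 8), 2, 8)
  F <- W0 %*% H0
  dec <- nmf_fit(F, k = 2L, seed = 3)
  expect_lt(dec$objective / sum(F^2), 1e-4)
  expect_true(all(dec$W >= 0) && all(dec$H >= 0))
  expect_error(nmf_fit(matrix(0, 3, 3), 2L), "all zero")
  expect_error(nmf_fit(matrix(-1, 3, 3), 2L), "non-negative")
})

test_that("diagnostic components recover planted block structure", {
  # two disjoint vertex blocks, one per target group
  set.seed(4)
  V <- 60L
  F <- matrix(0L, V, 8L)
  F[1:30, 1:4] <- rbinom(30 * 4, 1, 0.9)
  F[31:60, 5:8] <- rbinom(30 * 4, 1, 0.9)
  target_of <- rep(1:2, each = 4L)
  dc <- diagnostic_components(F, target_of, k = 2L, seed = 5)
  cd1 <- dc[["1"]]$C_D; cd2 <- dc[["2"]]$C_D
  expect_gt(mean(cd1[1:30]), 0.6)
  expect_lt(mean(cd1[31:60]), 0.2)
  expect_gt(mean(cd2[31:60]), 0.6)
  expect_equal(cd1 + dc[["1"]]$C_N, rep(1, V))
  expect_equal(max(cd1), 1)

  # threshold above all loadings: zero weights, one warning per target
  w <- capture_warnings(dc0 <- diagnostic_components(F, target_of, k = 2L,
                                                     loading_threshold = 1e9,
                                                     seed = 5))
  expect_length(w, 2L)
  expect_match(w, "no contributing", all = TRUE)
  expect_true(all(dc0[["1"]]$C_D == 0))
})

test_that("generalization set has the stated 2 x amps x conditions layout", {
  w <- tiny_world()
  m <- w$model
  tg <- list(ground_truth = synthesize_vertices(rnorm(8), w$factors, m),
             factors = w$factors,
             C_D = runif(m$n_vertices))
  gset <- build_generalization_set(list(t1 = tg), m)
  expect_equal(nrow(gset$manifest), 50L)
  expect_equal(nrow(gset$faces), 50L)
  expect_equal(sort(unique(gset$manifest$alpha)),
               c(0.33, 0.67, 1, 1.33, 1.67))
  expect_equal(length(unique(gset$manifest$condition)), 5L)

  # count contract holds for any configuration
  gs2 <- build_generalization_set(list(t1 = tg, t2 = tg), m,
                                  amps = c(0.5, 1),
                                  conditions = c("view_0", "age_80"))
  expect_equal(nrow(gs2$manifest), 2L * 2L * 2L * 2L)

  # alpha = 1, C_D = 1, frontal view: exactly the ground truth
  tg1 <- tg; tg1$C_D <- rep(1, m$n_vertices)
  gs1 <- build_generalization_set(list(t1 = tg1), m, amps = 1,
                                  conditions = "view_0")
  expect_equal(gs1$faces[1, ], tg1$ground_truth)

  # alpha = 0 appended: categorical average
  gs0 <- build_generalization_set(list(t1 = tg), m, amps = 0,
                                  conditions = "view_0")
  expect_equal(gs0$faces[1, ], gmf_prototype(w$factors, m))

  expect_error(build_generalization_set(list(t1 = tg), m,
                                        conditions = "upside_down"),
               "unknown")
})

test_that("condition edits change the demographic prototype as labeled", {
  w <- tiny_world()
  tg <- list(ground_truth = gmf_prototype(w$factors, w$model),
             factors = w$factors, C_D = rep(0, w$model$n_vertices))
  gs <- build_generalization_set(list(t1 = tg), w$model, amps = 1,
                                 conditions = c("view_0", "age_80"))
  f80 <- w$factors; f80$age <- 80
  expect_equal(gs$faces[gs$manifest$condition == "age_80" &
                          gs$manifest$diagnosticity == "diagnostic", ],
               gmf_prototype(f80, w$model))
  expect_equal(gs$manifest$view[gs$manifest$condition == "view_0"],
               rep(0, 2))
})

test_that("identification chooses its own diagnostic face and breaks ties low", {
  w <- tiny_world()
  m <- w$model
  set.seed(6)
  mk_target <- function() {
    comps <- rnorm(8)
    list(components = comps, factors = w$factors,
         ground_truth = synthesize_vertices(comps, w$factors, m),
         C_D = rep(1, m$n_vertices))
  }
  tgs <- list(t1 = mk_target(), t2 = mk_target())
  gset <- build_generalization_set(tgs, m, conditions = "view_0")
  responders <- lapply(tgs, function(tg) {
    function(face) -sum((project_components(face, tg$factors, m) -
                           tg$components)^2)
  })
  res <- simulate_identification(responders, gset)
  # a target's own diagnostic face at the top amplification is identified
  top <- res[res$alpha == 1.67 & res$diagnosticity == "diagnostic", ]
  expect_true(all(top$accuracy == 1))

  # all-identical scores: lowest target index with a tie log
  same <- list(t1 = function(face) sum(face), t2 = function(face) sum(face))
  expect_message(res2 <- simulate_identification(same, gset), "tied")
  expect_true(all(res2$choice == "t1"))

  expect_error(simulate_identification(
    list(t1 = function(face) 1, t2 = function(face) sum(face)), gset),
    "constant")
})

test_that("accuracy error is elementwise with a per-condition summary", {
  expect_equal(accuracy_error(c(1, 0, 1), c(1, 0, 1))$abs_error, c(0, 0, 0))
  expect_equal(accuracy_error(1, 0.8)$abs_error, 0.2)
  set.seed(7)
  ma <- rbinom(40, 1, 0.7)
  ra <- sample(seq(0, 1, 0.2), 40, replace = TRUE)
  cond <- rep(c("a", "b"), 20)
  ae <- accuracy_error(ma, ra, condition = cond, n_boot = 200L, seed = 8)
  expect_equal(ae$abs_error, abs(ma - ra))
  expect_equal(nrow(ae$summary), 2L)
  expect_true(all(ae$summary$lower <= ae$summary$median + 1e-12))
  expect_error(accuracy_error(1:3, 1:2), "mismatch")
})
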