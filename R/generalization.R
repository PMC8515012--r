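# Diagnostic/non-diagnostic stimulus construction and out-of-distribution
# identification testing.

#' Classify vertices as faithfully reconstructed
#'
#' A vertex is "faithful" when the chance reconstruction sits further from
#' the ground truth than the actual reconstruction does:
#' `|chance - truth| > |recon - truth|` (strict, so a reconstruction no
#' better than chance is not faithful). Distances are signed per vertex
#' (inside/outside the categorical average).
#'
#' @param recon_dist,chance_dist,truth_dist numeric vectors (or matrices) of
#'   per-vertex signed distances.
#' @return logical vector/matrix of the same shape.
#' @export
classify_faithful <- function(recon_dist, chance_dist, truth_dist) {
  if (anyNA(recon_dist) || anyNA(chance_dist) || anyNA(truth_dist))
    stop("NaN/NA distances")
  abs(chance_dist - truth_dist) > abs(recon_dist - truth_dist)
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Frobenius-norm NMF `F ~ W H` with seeded non-negative random
#' initialization, multiplicative updates, an iteration cap and a relative
#' convergence tolerance.
#'
#' @param F non-negative matrix (rows x columns).
#' @param k rank.
#' @param max_iter iteration cap (default 500).
#' @param tol relative change tolerance on the objective (default 1e-6).
#' @param seed init seed.
#' @return list with `W` (rows x k), `H` (k x columns), `iterations`,
#'   `objective`.
#' @export
nmf_fit <- function(F, k = 8L, max_iter = 500L, tol = 1e-6, seed = 1L) {
  F <- as.matrix(F)
  if (any(F < 0)) stop("F must be non-negative")
  if (all(F == 0)) stop("F is all zero; factorization undefined")
  set.seed(seed)
  nr <- nrow(F); nc <- ncol(F)
  W <- matrix(stats::runif(nr * k, 0.1, 1), nr, k)
  H <- matrix(stats::runif(k * nc, 0.1, 1), k, nc)
  eps <- 1e-12
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, F) / (crossprod(W) %*% H + eps))
    W <- W * (F %*% t(H)) / (W %*% tcrossprod(H) + eps)
    obj <- sum((F - W %*% H)^2)
    if (is.finite(obj_old) && abs(obj_old - obj) < tol * max(obj_old, eps)) {
      obj_old <- obj; break
    }
    obj_old <- obj
  }
  list(W = W, H = H, iterations = it, objective = obj_old)
}

#' Diagnostic components from a faithfulness matrix
#'
#' Decomposes a binary vertices x (observer, target) faithfulness matrix by
#' rank-k NMF. A component is taken to contribute to a target's group
#' representation when the median of its loadings over that target's columns
#' exceeds `loading_threshold`. The diagnostic weight `C_D` of a target is
#' the per-vertex maximum over contributing components' basis columns,
#' normalized to a maximum of 1; its complement is `C_N = 1 - C_D`.
#'
#' @param F binary matrix, vertices x (n_observers * n_targets), columns
#'   observer-major within target (all observers of target 1 first).
#' @param target_of integer vector giving the target of each column.
#' @param k NMF rank (default 8).
#' @param loading_threshold median-loading threshold (default 0.1).
#' @param seed NMF init seed.
#' @return named list (one entry per target) of class `diagnostic_components`
#'   elements: `C_D`, `C_N`, `contributing`; plus attributes `W`, `H`.
#' @export
diagnostic_components <- function(F, target_of, k = 8L,
                                  loading_threshold = 0.1, seed = 1L) {
  F <- as.matrix(F)
  if (length(target_of) != ncol(F)) stop("target_of length != ncol(F)")
  dec <- nmf_fit(F, k = k, seed = seed)
  targets <- unique(target_of)
  out <- lapply(targets, function(tg) {
    med <- apply(dec$H[, target_of == tg, drop = FALSE], 1L, stats::median)
    contributing <- which(med > loading_threshold)
    if (length(contributing) == 0L) {
      warning("no contributing components for target ", tg, "; C_D = 0")
      C_D <- rep(0, nrow(F))
    } else {
      C_D <- apply(dec$W[, contributing, drop = FALSE], 1L, max)
      if (max(C_D) > 0) C_D <- C_D / max(C_D)
    }
    structure(list(C_D = C_D, C_N = 1 - C_D, contributing = contributing),
              class = "diagnostic_components")
  })
  names(out) <- as.character(targets)
  attr(out, "W") <- dec$W
  attr(out, "H") <- dec$H
  out
}

generalization_conditions <- function() {
  c("view_m30", "view_0", "view_p30", "age_80", "sex_swap")
}

apply_condition <- function(factors, condition) {
  f <- factors
  view <- 0
  if (condition == "view_m30") view <- -30
  else if (condition == "view_p30") view <- 30
  else if (condition == "view_0") view <- 0
  else if (condition == "age_80") f$age <- 80
  else if (condition == "sex_swap") f$sex <- 1 - as.numeric(f$sex)
  else stop("unknown generalization condition: ", condition)
  list(factors = f, view = view)
}

#' Build the diagnostic/non-diagnostic generalization stimulus set
#'
#' Per target: two levels of diagnosticity (diagnostic weights `C_D` vs
#' their complement `C_N`) crossed with the amplification levels and the
#' generalization conditions — by default `2 x 5 x 5 = 50` stimuli. Faces
#' are per-vertex mixtures of the target's ground truth and the categorical
#' average; viewing-angle conditions are metadata labels (no renderer),
#' while the age and sex conditions re-derive the categorical average from
#' edited factor values.
#'
#' @param targets named list; each element needs `ground_truth` (flat V*3),
#'   `factors` (one-row data.frame), `C_D` (length V in `[0, 1]`).
#' @param model fitted `gmf_model`.
#' @param amps amplification levels (default 0.33, 0.67, 1, 1.33, 1.67).
#' @param conditions condition labels (default the five standard ones:
#'   three viewing angles, age set to 80, swapped sex).
#' @return list with `manifest` (data.frame: target, diagnosticity, alpha,
#'   condition, view) and `faces` (stimulus x V*3 matrix, rows aligned).
#' @export
build_generalization_set <- function(targets, model,
                                     amps = c(0.33, 0.67, 1, 1.33, 1.67),
                                     conditions = generalization_conditions()) {
  rows <- list(); faces <- list(); i <- 0L
  for (tn in names(targets)) {
    tg <- targets[[tn]]
    for (diag_level in c("diagnostic", "nondiagnostic")) {
      C <- if (diag_level == "diagnostic") tg$C_D else 1 - tg$C_D
      for (a in amps) for (cond in conditions) {
        ed <- apply_condition(tg$factors, cond)
        proto <- gmf_prototype(ed$factors, model)
        i <- i + 1L
        faces[[i]] <- suppressMessages(
          construct_amplified_face(tg$ground_truth, proto, C, a))
        rows[[i]] <- data.frame(target = tn, diagnosticity = diag_level,
                                alpha = a, condition = cond, view = ed$view,
                                stringsAsFactors = FALSE)
      }
    }
  }
  list(manifest = do.call(rbind, rows), faces = do.call(rbind, faces))
}

#' Simulated identification of generalization stimuli
#'
#' Each target's responder scores every stimulus; scores are min-max
#' normalized within target across the stimulus set (guarding against
#' per-target rating biases), and the choice is the target with the maximum
#' normalized score (ties toward the lowest target index, counted).
#' Accuracy per stimulus is binary: choice equals the stimulus's true
#' target.
#'
#' @param responders named list (one per target) of functions mapping a flat
#'   face vector to a predicted rating; names must match manifest targets.
#' @param stimuli output of [build_generalization_set()].
#' @return data.frame: manifest columns plus `choice` and `accuracy`;
#'   attribute `n_ties`.
#' @export
simulate_identification <- function(responders, stimuli) {
  man <- stimuli$manifest
  targets <- names(responders)
  P <- sapply(targets, function(tn)
    apply(stimuli$faces, 1L, responders[[tn]]))
  P <- rbind(P)  # stimuli x targets
  for (j in seq_len(ncol(P))) {
    rng <- range(P[, j])
    if (rng[1] == rng[2])
      stop("constant predictions for target ", targets[j],
           "; normalization undefined")
    P[, j] <- (P[, j] - rng[1]) / (rng[2] - rng[1])
  }
  choice_i <- max.col(P, ties.method = "first")
  rowmax <- P[cbind(seq_len(nrow(P)), choice_i)]
  n_ties <- sum(rowSums(P == rowmax) > 1L)
  if (n_ties > 0L) message(n_ties, " stimulus/stimuli had tied scores; ",
                           "lowest target index chosen")
  out <- cbind(man,
               choice = targets[choice_i],
               accuracy = as.numeric(targets[choice_i] == man$target))
  attr(out, "n_ties") <- n_ties
  out
}

#' Absolute accuracy error against reference behavior
#'
#' Elementwise `|model - reference|` accuracy error, optionally summarized
#' per condition by the median with a bootstrap percentile interval (a
#' descriptive substitute for a hierarchical ordinal model).
#'
#' @param model_acc binary model accuracies.
#' @param reference_acc reference accuracies on the same stimuli (e.g. in
#'   steps of 0.2 when each stimulus was judged five times).
#' @param condition optional grouping factor for the summary.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return list with `abs_error` and, when `condition` is given, `summary`
#'   (condition, median, lower, upper).
#' @export
accuracy_error <- function(model_acc, reference_acc, condition = NULL,
                           n_boot = 1000L, seed = 1L) {
  if (length(model_acc) != length(reference_acc)) stop("length mismatch")
  err <- abs(model_acc - reference_acc)
  out <- list(abs_error = err)
  if (!is.null(condition)) {
    set.seed(seed)
    out$summary <- do.call(rbind, lapply(split(err, condition), function(e) {
      boots <- vapply(seq_len(n_boot), function(b)
        stats::median(sample(e, replace = TRUE)), numeric(1))
      data.frame(median = stats::median(e),
                 lower = unname(stats::quantile(boots, 0.025)),
                 upper = unname(stats::quantile(boots, 0.975)))
    }))
    out$summary$condition <- rownames(out$summary)
    rownames(out$summary) <- NULL
  }
  out
}
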