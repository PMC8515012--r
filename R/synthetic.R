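# Synthetic world generators: face databases, stimulus sets, embeddings and
# simulated observers, all pure functions of (config, seed).

random_orthonormal <- function(nrow, ncol) {
  # columns orthonormal; requires nrow >= ncol
  qr.Q(qr(matrix(stats::rnorm(nrow * ncol), nrow, ncol)))[, seq_len(ncol), drop = FALSE]
}

#' Generate a synthetic face database
#'
#' Emulates a 3D-scan face database: vertex clouds on a sphere-like layout,
#' demographic factor effects (sex, age, three-level ethnicity, all
#' interactions) and a low-rank residual identity structure of known rank.
#' The generating parameters are attached as the `ground_truth` attribute for
#' parameter-recovery tests.
#'
#' @param n_exemplars number of scanned identities (default 355).
#' @param n_vertices vertices per face (default 4735; coordinates are
#'   interleaved xyz, giving `n_vertices * 3` columns).
#' @param rank rank of the residual identity structure (default 40).
#' @param factor_effect_sd scale of demographic coefficients (length units).
#' @param residual_sd scale of the leading residual direction.
#' @param with_texture also generate a single-band texture block of
#'   `texture_px` values with its own low-rank structure.
#' @param texture_px texture values per face.
#' @param seed integer seed; identical seeds give identical databases.
#' @return object of class `face_db`: list with `shape`, optional `texture`,
#'   `factors`, `ids`; attribute `ground_truth` holds the generating
#'   `A0`, `U0`, `s0` (and texture analogues) plus the base sphere.
#' @export
generate_face_database <- function(n_exemplars = 355L, n_vertices = 4735L,
                                   rank = 40L, factor_effect_sd = 1,
                                   residual_sd = 1, with_texture = FALSE,
                                   texture_px = 4L * n_vertices, seed = 1L) {
  n_design <- 12L
  if (n_exemplars < n_design + 1L)
    stop("n_exemplars must exceed the ", n_design, " design columns")
  if (rank > n_exemplars - n_design)
    stop("rank must be <= n_exemplars - ", n_design)
  set.seed(seed)
  d3 <- n_vertices * 3L

  factors <- data.frame(
    sex = stats::rbinom(n_exemplars, 1L, 0.5),
    age = stats::runif(n_exemplars, 20, 70),
    ethnicity = factor(sample(c("east_asian", "south_asian", "west_european"),
                              n_exemplars, replace = TRUE),
                       levels = c("east_asian", "south_asian", "west_european"))
  )
  dm <- build_design_matrix(factors)
  X <- dm$values

  # base head: unit-ish sphere via Fibonacci lattice, shared by all exemplars
  i <- seq_len(n_vertices) - 0.5
  phi <- acos(1 - 2 * i / n_vertices)
  theta <- pi * (1 + sqrt(5)) * i
  base <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi)) * 100
  base_flat <- as.vector(t(base))  # interleaved xyz

  A0 <- matrix(stats::rnorm(ncol(X) * d3, sd = factor_effect_sd), ncol(X), d3)
  A0[1L, ] <- A0[1L, ] + base_flat  # constant term carries the base head

  gen_lowrank <- function(d, r, sd0) {
    U0 <- random_orthonormal(d, r)
    s0 <- sd0 * 0.85^(seq_len(r) - 1L)      # geometric spectrum
    Z <- matrix(stats::rnorm(n_exemplars * r), n_exemplars, r)
    list(U0 = U0, s0 = s0, E = Z %*% (t(U0) * s0))
  }
  rs <- if (rank > 0L) gen_lowrank(d3, rank, residual_sd) else
    list(U0 = NULL, s0 = numeric(0), E = matrix(0, n_exemplars, d3))
  shape <- X %*% A0 + rs$E

  db <- list(shape = shape, factors = factors,
             ids = sprintf("ex%04d", seq_len(n_exemplars)))
  gt <- list(A0 = A0, U0 = rs$U0, s0 = rs$s0, base = base_flat, design = dm)
  if (with_texture) {
    A0t <- matrix(stats::rnorm(ncol(X) * texture_px, sd = factor_effect_sd),
                  ncol(X), texture_px)
    rt <- gen_lowrank(texture_px, min(rank, texture_px), residual_sd)
    db$texture <- X %*% A0t + rt$E
    gt$A0_texture <- A0t; gt$U0_texture <- rt$U0; gt$s0_texture <- rt$s0
  }
  attr(db, "ground_truth") <- gt
  class(db) <- "face_db"
  db
}

#' Generate a random stimulus set
#'
#' Draws identity components from an isotropic normal in the model's
#' unit-variance component convention, with demographic factors fixed (as in
#' a familiarity experiment, where stimuli share the target's demographics).
#' Texture components are drawn alongside when the model carries texture.
#'
#' @param model fitted `gmf_model`.
#' @param n_faces number of random identities.
#' @param component_sd standard deviation of components (default 1, i.e. the
#'   database's own identity variability).
#' @param factors one-row data.frame of fixed demographic values.
#' @param seed integer seed.
#' @return object of class `stimulus_set`: list with `components`
#'   (n_faces x K), optional `texture_components`, `factors`, `ids`.
#' @export
generate_stimulus_set <- function(model, n_faces, component_sd = 1,
                                  factors, seed = 1L) {
  stopifnot(inherits(model, "gmf_model"))
  set.seed(seed)
  K <- model$K_shape
  comps <- matrix(stats::rnorm(n_faces * K, sd = component_sd), n_faces, K)
  out <- list(components = comps, factors = factors,
              ids = sprintf("f%06d", seq_len(n_faces)))
  if (!is.null(model$K_texture))
    out$texture_components <- matrix(
      stats::rnorm(n_faces * model$K_texture, sd = component_sd),
      n_faces, model$K_texture)
  class(out) <- "stimulus_set"
  out
}

#' Specify a simulated observer
#'
#' An observer holds a hidden internal template in component space and a
#' per-component relevance weighting. Two response families are available:
#' `"distance"` scores a candidate by the negative weighted squared distance
#' of its components to the template; `"linear"` scores by a weighted linear
#' projection (a linear "shape receptive field"). Gaussian noise of
#' `noise_sd` is added to the score.
#'
#' @param template_components hidden target identity (length K).
#' @param srf_weights per-component relevance weights; at least one nonzero.
#' @param noise_sd score noise standard deviation (>= 0).
#' @param type `"distance"` or `"linear"`.
#' @param seed integer seed used when simulating sessions.
#' @return object of class `observer_spec`.
#' @export
observer_spec <- function(template_components, srf_weights = NULL,
                          noise_sd = 0, type = c("distance", "linear"),
                          seed = 1L) {
  type <- match.arg(type)
  if (is.null(srf_weights)) srf_weights <- rep(1, length(template_components))
  stopifnot(length(srf_weights) == length(template_components), noise_sd >= 0)
  if (all(srf_weights == 0)) stop("at least one srf weight must be nonzero")
  structure(list(template_components = template_components,
                 srf_weights = srf_weights, noise_sd = noise_sd,
                 type = type, seed = seed),
            class = "observer_spec")
}

observer_score <- function(observer, components) {
  # components: n x K matrix; returns noiseless scores
  if (observer$type == "distance") {
    D <- sweep(components, 2L, observer$template_components)
    -drop(D^2 %*% observer$srf_weights)
  } else {
    drop(components %*% observer$srf_weights)
  }
}

#' Simulate a choose-and-rate session
#'
#' Stimuli are taken in consecutive groups of `array_size`; on each trial the
#' observer chooses the candidate with the highest (noisy) similarity score
#' and the chosen score is rated on a 6-point scale by equipopulated-quantile
#' binning of the chosen scores within the session — a monotone map from
#' similarity to rating that uses the whole scale.
#'
#' @param observer an `observer_spec`.
#' @param stimuli a `stimulus_set` with exactly
#'   `trials_per_session * array_size` faces.
#' @param trials_per_session number of trials (default 1800).
#' @param array_size candidates per trial (default 6).
#' @param n_rating_bins rating scale size (default 6).
#' @return object of class `session`: data.frame with candidate ids, chosen
#'   index (1-based), rating; attributes `chosen_components`,
#'   `chosen_scores`, `arrays` (trial x array_size index matrix).
#' @export
simulate_session <- function(observer, stimuli, trials_per_session = 1800L,
                             array_size = 6L, n_rating_bins = 6L) {
  n <- nrow(stimuli$components)
  if (n != trials_per_session * array_size)
    stop("stimulus count ", n, " != trials_per_session * array_size = ",
         trials_per_session * array_size)
  set.seed(observer$seed)
  scores <- observer_score(observer, stimuli$components) +
    stats::rnorm(n, sd = observer$noise_sd)
  arrays <- matrix(seq_len(n), nrow = trials_per_session,
                   ncol = array_size, byrow = TRUE)
  sc <- matrix(scores[t(arrays)], nrow = trials_per_session,
               ncol = array_size, byrow = TRUE)
  chosen <- max.col(sc, ties.method = "first")
  chosen_idx <- arrays[cbind(seq_len(trials_per_session), chosen)]
  chosen_scores <- sc[cbind(seq_len(trials_per_session), chosen)]
  rating <- bin_equipopulated(chosen_scores, B = n_rating_bins)$labels + 1L
  out <- data.frame(trial = seq_len(trials_per_session),
                    chosen_index = chosen,
                    chosen_id = stimuli$ids[chosen_idx],
                    rating = rating)
  attr(out, "arrays") <- arrays
  attr(out, "chosen_stimulus") <- chosen_idx
  attr(out, "chosen_components") <-
    stimuli$components[chosen_idx, , drop = FALSE]
  attr(out, "chosen_scores") <- chosen_scores
  class(out) <- c("session", "data.frame")
  out
}

#' Specify a synthetic embedding space
#'
#' Stands in for the compressed embedding layer of a trained network:
#' channels are linear images of shape and/or texture identity components at
#' configurable fidelity, optionally passed through a saturating
#' nonlinearity, plus channel noise. Fidelities must sum to at most 1.
#'
#' @param name identifier.
#' @param dim number of channels (e.g. 64 or 512).
#' @param shape_fidelity,texture_fidelity mixing weights in `[0, 1]`.
#' @param nonlinearity `"none"` or `"squash"` (tanh).
#' @param noise_sd channel noise standard deviation.
#' @param seed integer seed for the random orthonormal channel maps.
#' @return object of class `embedding_spec`.
#' @export
embedding_spec <- function(name, dim = 64L, shape_fidelity = 1,
                           texture_fidelity = 0,
                           nonlinearity = c("none", "squash"),
                           noise_sd = 0, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(dim >= 1L, shape_fidelity >= 0, texture_fidelity >= 0,
            shape_fidelity + texture_fidelity <= 1)
  structure(list(name = name, dim = as.integer(dim),
                 shape_fidelity = shape_fidelity,
                 texture_fidelity = texture_fidelity,
                 nonlinearity = nonlinearity, noise_sd = noise_sd,
                 seed = seed),
            class = "embedding_spec")
}

#' Generate a synthetic embedding predictor space
#'
#' Channels are built as
#' `shape_fidelity * C_s W_s + texture_fidelity * C_t W_t + noise`, with
#' `W` drawn once per seed with orthonormal rows (so at fidelity 1 and zero
#' noise the components are exactly linearly decodable), then optionally
#' squashed and finally standardized per channel.
#'
#' @param spec an `embedding_spec`.
#' @param stimuli a `stimulus_set`.
#' @param model fitted `gmf_model` (provides component dimensions).
#' @return a `predictor_space` with a single subspace named after the spec.
#' @export
generate_embedding <- function(spec, stimuli, model) {
  stopifnot(inherits(spec, "embedding_spec"))
  set.seed(spec$seed)
  n <- nrow(stimuli$components)
  K <- ncol(stimuli$components)
  if (spec$dim < K && spec$shape_fidelity > 0)
    warning("embedding dim < K; shape components not fully recoverable")
  Ws <- t(random_orthonormal(max(spec$dim, K), K))[, seq_len(spec$dim), drop = FALSE]
  E <- spec$shape_fidelity * (stimuli$components %*% Ws)
  if (spec$texture_fidelity > 0) {
    if (is.null(stimuli$texture_components))
      stop("texture fidelity requested but stimuli carry no texture components")
    Kt <- ncol(stimuli$texture_components)
    Wt <- t(random_orthonormal(max(spec$dim, Kt), Kt))[, seq_len(spec$dim), drop = FALSE]
    E <- E + spec$texture_fidelity * (stimuli$texture_components %*% Wt)
  }
  if (spec$noise_sd > 0)
    E <- E + matrix(stats::rnorm(n * spec$dim, sd = spec$noise_sd), n, spec$dim)
  if (spec$nonlinearity == "squash") E <- tanh(E)
  sds <- apply(E, 2L, stats::sd)
  sds[sds == 0] <- 1
  E <- sweep(sweep(E, 2L, colMeans(E)), 2L, sds, "/")
  predictor_space(spec$name, E,
                  subspaces = stats::setNames(list(seq_len(spec$dim)), spec$name))
}

#' Experiment design bookkeeping
#'
#' Enumerates the design of a choose-and-rate familiarity experiment: trials
#' per target, candidates per array, random faces per target set, totals
#' across targets, and the size of the pooled decoding stimulus set.
#'
#' @param n_targets familiar target identities (default 4).
#' @param trials_per_target trials per observer and target (default 1800).
#' @param array_size faces per array (default 6).
#' @return list of counts: `trials_total`, `faces_per_target`,
#'   `decoding_total`, plus the inputs.
#' @export
experiment_design <- function(n_targets = 4L, trials_per_target = 1800L,
                              array_size = 6L) {
  faces_per_target <- trials_per_target * array_size
  list(n_targets = n_targets,
       trials_per_target = trials_per_target,
       array_size = array_size,
       trials_total = n_targets * trials_per_target,
       faces_per_target = faces_per_target,
       decoding_total = n_targets * faces_per_target)
}

#' Rendering-grid enumeration
#'
#' Counts the identities and grid cells of a full synthesis grid: random
#' identity residuals crossed with sex and ethnicity, plus familiar targets,
#' rendered at every combination of age, emotion, and horizontal/vertical
#' viewing and lighting angles, optionally doubled across two generative
#' model versions.
#'
#' @param n_residuals random identity residuals (default 500).
#' @param n_sex,n_ethnicity demographic levels crossed with residuals.
#' @param n_targets familiar identities appended (default 4).
#' @param n_ages,n_emotions,n_view,n_light rendering factor levels (viewing
#'   and lighting each have horizontal and vertical axes).
#' @param n_versions generative-model versions (default 2).
#' @return list with `identities`, `grid_cells`, `grid_cells_all_versions`.
#' @export
rendering_grid <- function(n_residuals = 500L, n_sex = 2L, n_ethnicity = 2L,
                           n_targets = 4L, n_ages = 3L, n_emotions = 7L,
                           n_view = 3L, n_light = 3L, n_versions = 2L) {
  identities <- n_residuals * n_sex * n_ethnicity + n_targets
  grid_cells <- identities * n_ages * n_emotions * n_view^2 * n_light^2
  list(identities = identities,
       grid_cells = grid_cells,
       grid_cells_all_versions = grid_cells * n_versions)
}
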