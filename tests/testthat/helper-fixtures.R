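# Shared tiny-world fixtures, built once per test run.

tiny_world <- local({
  cache <- new.env()
  function(seed = 3L, rank = 8L, K = 8L) {
    key <- paste(seed, rank, K, sep = "_")
    if (is.null(cache[[key]])) {
      db <- generate_face_database(n_exemplars = 60L, n_vertices = 60L,
                                   rank = rank, with_texture = TRUE,
                                   texture_px = 120L, seed = seed)
      model <- suppressWarnings(gmf_fit(db, K = K, K_texture = K))
      cache[[key]] <- list(db = db, model = model,
                           factors = db$factors[1L, , drop = FALSE])
    }
    cache[[key]]
  }
})

# a complete tiny session: observer, stimuli, session, chosen features
tiny_session <- function(world, obs_seed = 10L, stim_seed = 20L,
                         noise_sd = 0, type = "linear", trials = 180L,
                         template = NULL, weights = NULL) {
  K <- world$model$K_shape
  set.seed(obs_seed)
  if (is.null(template)) template <- stats::rnorm(K)
  if (is.null(weights)) weights <- stats::runif(K, 0.2, 1)
  obs <- observer_spec(template, weights, noise_sd = noise_sd, type = type,
                       seed = obs_seed + 1L)
  stim <- generate_stimulus_set(world$model, trials * 6L,
                                factors = world$factors, seed = stim_seed)
  ses <- simulate_session(obs, stim, trials)
  list(observer = obs, stimuli = stim, session = ses,
       chosen = attr(ses, "chosen_stimulus"),
       chosen_components = attr(ses, "chosen_components"))
}

full_design_factors <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  data.frame(sex = rep(0:1, length.out = n),
             age = seq(20, 70, length.out = n),
             ethnicity = factor(rep(c("a", "b", "c"), length.out = n)))
}
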