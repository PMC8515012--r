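# End-to-end orchestration: configuration profiles, staged execution with
# serialized artifacts and provenance, and summary reporting.

#' Build a run configuration
#'
#' Two profiles are provided: `"tiny"` (4 observers x 2 targets x 180
#' trials, small meshes; the test default, finishing in minutes on one CPU)
#' and `"paper-scale"` (14 observers x 4 targets x 1800 trials on full-size
#' meshes). Every stochastic stage derives its seed from the master seed, so
#' a config fully determines a run.
#'
#' @param profile `"tiny"` or `"paper-scale"`.
#' @param seed master integer seed.
#' @param ... named overrides of top-level config entries.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(profile = c("tiny", "paper-scale"), seed = 1L, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "tiny") {
    list(db = list(n_exemplars = 60L, n_vertices = 60L, rank = 8L,
                   factor_effect_sd = 1, residual_sd = 1,
                   with_texture = TRUE, texture_px = 120L),
         K = 8L,
         experiment = list(n_observers = 4L, n_targets = 2L,
                           trials = 180L, array_size = 6L, fold_len = 20L),
         observer = list(noise_frac = 0.3, type = "distance"),
         embeddings = list(
           list(name = "emb_shape", dim = 32L, shape_fidelity = 0.9,
                texture_fidelity = 0, noise_sd = 0.2),
           list(name = "emb_texture", dim = 32L, shape_fidelity = 0,
                texture_fidelity = 0.9, noise_sd = 0.2)),
         info = list(n_bins = 3L, n_perm = 25L, percentile = 95),
         revcor = list(amp_max = 50, amp_step = 0.5, n_chance = 10L),
         generalization = list(amps = c(0.33, 0.67, 1, 1.33, 1.67),
                               k_nmf = 4L, loading_threshold = 0.1,
                               n_validators = 5L))
  } else {
    list(db = list(n_exemplars = 355L, n_vertices = 4735L, rank = 40L,
                   factor_effect_sd = 1, residual_sd = 1,
                   with_texture = TRUE, texture_px = 9470L),
         K = 40L,
         experiment = list(n_observers = 14L, n_targets = 4L,
                           trials = 1800L, array_size = 6L, fold_len = 200L),
         observer = list(noise_frac = 0.3, type = "distance"),
         embeddings = list(
           list(name = "emb_shape", dim = 64L, shape_fidelity = 0.9,
                texture_fidelity = 0, noise_sd = 0.2),
           list(name = "emb_texture", dim = 64L, shape_fidelity = 0,
                texture_fidelity = 0.9, noise_sd = 0.2)),
         info = list(n_bins = 3L, n_perm = 100L, percentile = 95),
         revcor = list(amp_max = 50, amp_step = 0.5, n_chance = 10L),
         generalization = list(amps = c(0.33, 0.67, 1, 1.33, 1.67),
                               k_nmf = 8L, loading_threshold = 0.1,
                               n_validators = 5L))
  }
  cfg <- utils::modifyList(base, list(...))
  cfg$profile <- profile
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed) || is.na(cfg$seed))
    stop("config is missing a master seed")
  needed <- c("db", "K", "experiment", "observer", "embeddings", "info",
              "revcor", "generalization")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0L)
    stop("config is missing section(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

stage_seed <- function(cfg, stage, o = 0L, t = 0L) {
  # deterministic per-stage seed, kept within 32-bit range
  offs <- c(db = 11L, target = 23L, stimuli = 31L, observer = 47L,
            embedding = 59L, fit = 67L, info = 71L, revcor = 83L,
            generalization = 97L)
  (cfg$seed * 1009L + offs[[stage]] * 101L + o * 13L + t) %% 2147483563L
}

log_provenance <- function(run_dir, stage, artifact, seed) {
  line <- data.frame(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     stage = stage, artifact = artifact, seed = seed,
                     config_hash = readLines(file.path(run_dir, "config.hash")))
  utils::write.table(line, file.path(run_dir, "provenance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     col.names = !file.exists(file.path(run_dir, "provenance.tsv")),
                     append = file.exists(file.path(run_dir, "provenance.tsv")))
}

fold_mean_responder <- function(fit, to_features) {
  # average the per-fold standardized models into one responder over faces
  function(face) {
    x <- to_features(face)
    mean(vapply(fit$folds, function(f)
      sum((x - f$x_stats$center) / f$x_stats$scale * f$weights) + f$y_center,
      numeric(1)))
  }
}

signed_normal_distance <- function(face, prototype, normals) {
  D <- matrix(face - prototype, ncol = 3L, byrow = TRUE)
  rowSums(D * normals)
}

#' Run the full analysis pipeline
#'
#' Executes the stages generate -> fit -> evaluate -> revcor -> generalize
#' -> report in order, writing each stage's artifacts (TSV tables, PLY
#' templates, serialized fits) under `out_dir` together with a provenance
#' log (config hash, stage, seed). A failed stage halts the run with the
#' stage name; completed artifacts are preserved.
#'
#' @param cfg a `run_config`.
#' @param out_dir run directory (created).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(cfg, cfg_path)
  writeLines(unname(tools::md5sum(cfg_path)), file.path(out_dir, "config.hash"))
  stage <- "generate"
  tryCatch({
    st <- run_stage_generate(cfg, out_dir)
    stage <- "fit"
    st <- run_stage_fit(cfg, out_dir, st)
    stage <- "evaluate"
    run_stage_evaluate(cfg, out_dir, st)
    stage <- "revcor"
    st <- run_stage_revcor(cfg, out_dir, st)
    stage <- "generalize"
    run_stage_generalize(cfg, out_dir, st)
    stage <- "report"
    report(out_dir)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out_dir)
}

run_stage_generate <- function(cfg, out_dir) {
  ex <- cfg$experiment
  db <- do.call(generate_face_database,
                c(cfg$db, list(seed = stage_seed(cfg, "db"))))
  model <- gmf_fit(db, K = cfg$K, K_texture = cfg$K)
  save_gmf_model(model, file.path(out_dir, "gmf_model"))
  log_provenance(out_dir, "generate", "gmf_model", stage_seed(cfg, "db"))

  targets <- lapply(seq_len(ex$n_targets), function(t) {
    set.seed(stage_seed(cfg, "target", t = t))
    comps <- stats::rnorm(model$K_shape)
    # all targets share demographics so identification depends on identity
    # structure, not on demographic-prototype offsets
    factors <- data.frame(sex = 0L, age = 40,
                          ethnicity = factor("east_asian",
                                             levels = model$design_spec$ethnicity_levels))
    list(components = comps, factors = factors,
         vertices = synthesize_vertices(comps, factors, model))
  })
  names(targets) <- paste0("target", seq_len(ex$n_targets))

  sessions <- list(); stimuli <- list()
  for (o in seq_len(ex$n_observers)) for (t in seq_len(ex$n_targets)) {
    key <- sprintf("o%02d_t%d", o, t)
    stim <- generate_stimulus_set(model, ex$trials * ex$array_size,
                                  factors = targets[[t]]$factors,
                                  seed = stage_seed(cfg, "stimuli", o, t))
    set.seed(stage_seed(cfg, "observer", o, t))
    w <- stats::runif(model$K_shape, 0.2, 1)
    obs <- observer_spec(targets[[t]]$components, srf_weights = w,
                         type = cfg$observer$type,
                         seed = stage_seed(cfg, "observer", o, t) + 1L)
    sig_sd <- stats::sd(observer_score(obs, stim$components))
    obs$noise_sd <- cfg$observer$noise_frac * sig_sd
    ses <- simulate_session(obs, stim, ex$trials, ex$array_size)
    write_session_tsv(ses, file.path(out_dir, paste0("session_", key, ".tsv")))
    log_provenance(out_dir, "generate", paste0("session_", key),
                   stage_seed(cfg, "observer", o, t))
    sessions[[key]] <- list(session = ses, observer = obs)
    stimuli[[key]] <- stim
  }
  list(db = db, model = model, targets = targets, sessions = sessions,
       stimuli = stimuli)
}

run_stage_fit <- function(cfg, out_dir, st) {
  ex <- cfg$experiment
  fits <- list()
  for (key in names(st$sessions)) {
    ses <- st$sessions[[key]]$session
    stim <- st$stimuli[[key]]
    chosen <- attr(ses, "chosen_stimulus")
    spaces <- list(shape = predictor_space(
      "shape", stim$components[chosen, , drop = FALSE],
      subspaces = list(shape = seq_len(ncol(stim$components)))))
    for (es in cfg$embeddings) {
      spec <- do.call(embedding_spec,
                      c(es, list(seed = stage_seed(cfg, "embedding"))))
      emb <- generate_embedding(spec, stim, st$model)
      spaces[[es$name]] <- predictor_space(
        es$name, emb$values[chosen, , drop = FALSE], emb$subspaces)
    }
    fits[[key]] <- lapply(spaces, nested_cv_fit, ratings = ses$rating,
                          fold_len = ex$fold_len)
    pred <- do.call(cbind, lapply(fits[[key]], `[[`, "predictions"))
    out <- data.frame(trial = ses$trial, observed = ses$rating, pred)
    utils::write.table(out, file.path(out_dir, paste0("predictions_", key, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_provenance(out_dir, "fit", paste0("predictions_", key),
                   stage_seed(cfg, "fit"))
    saveRDS(fits[[key]], file.path(out_dir, paste0("fits_", key, ".rds")))
  }
  st$fits <- fits
  st
}

run_stage_evaluate <- function(cfg, out_dir, st) {
  info <- cfg$info
  rows <- list()
  for (key in names(st$fits)) {
    ses <- st$sessions[[key]]$session
    fits <- st$fits[[key]]
    y <- ses$rating
    shape_pred <- fits$shape$predictions
    for (sp in names(fits)) {
      fit <- fits[[sp]]
      for (b in seq_along(fit$folds)) {
        idx <- fit$folds[[b]]$test_idx
        p <- fit$predictions[idx]
        mi <- mutual_information_mm(bin_equipopulated(p, info$n_bins),
                                    bin_equipopulated(y[idx], info$n_bins))
        red <- if (sp == "shape") NA_real_ else
          redundancy_iccs(bin_equipopulated(p, info$n_bins),
                          bin_equipopulated(shape_pred[idx], info$n_bins),
                          bin_equipopulated(y[idx], info$n_bins))
        thr <- permutation_null(function(ys)
          mutual_information_mm(bin_equipopulated(p, info$n_bins),
                                bin_equipopulated(ys, info$n_bins)),
          y[idx], n_perm = info$n_perm, percentile = info$percentile,
          seed = stage_seed(cfg, "info") + b)
        rows[[length(rows) + 1L]] <- data.frame(
          key = key, space = sp, fold = b, mi_bits = mi,
          redundancy_bits = red, threshold_bits = as.numeric(thr),
          exceeds = mi > as.numeric(thr))
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(out_dir, "infotheory.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_provenance(out_dir, "evaluate", "infotheory", stage_seed(cfg, "info"))
  tab
}

run_stage_revcor <- function(cfg, out_dir, st) {
  rc <- cfg$revcor
  model <- st$model
  grid <- seq(0, rc$amp_max, by = rc$amp_step)
  comp_to_vertex <- function(comps, factors)
    synthesize_vertices(comps, factors, model)
  rows <- list(); templates <- list()
  for (key in names(st$sessions)) {
    t_id <- as.integer(sub(".*_t", "", key))
    tg <- st$targets[[t_id]]
    ses <- st$sessions[[key]]$session
    obs <- st$sessions[[key]]$observer
    stim <- st$stimuli[[key]]
    chosen_comps <- attr(ses, "chosen_components")
    chosen_vert <- chosen_comps %*% (t(model$U_shape) * model$scale_shape)
    chosen_vert <- sweep(chosen_vert, 2L,
                         gmf_prototype(tg$factors, model), "+")
    proto <- gmf_prototype(tg$factors, model)
    normals <- vertex_normals(proto)

    systems <- c(list(observed = ses$rating),
                 lapply(st$fits[[key]], `[[`, "predictions"))
    for (sys in names(systems)) {
      rcfit <- mass_univariate_fit(chosen_vert, systems[[sys]])
      responder <- if (sys == "observed") {
        function(face) observer_score(obs, rbind(
          project_components(face, tg$factors, model)))
      } else {
        fit <- st$fits[[key]][[sys]]
        if (sys == "shape")
          fold_mean_responder(fit, function(face)
            project_components(face, tg$factors, model))
        else {
          # embedding responders would need rendered images; the synthetic
          # stand-in maps the face back to components first
          fold_mean_responder(st$fits[[key]]$shape, function(face)
            project_components(face, tg$factors, model))
        }
      }
      tc <- suppressMessages(amplification_tuning(rcfit, responder, grid))
      templates[[paste(key, sys, sep = ".")]] <- tc$peak_face
      met_ver <- template_metrics(tc$peak_face, tg$vertices, proto, normals)
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, system = sys, peak_amp = tc$peak_amp,
        mae_veridical = met_ver$mae, r_veridical = met_ver$r_inout)
    }
    # humanness: distance of each model template to the observed template
    obs_tpl <- templates[[paste(key, "observed", sep = ".")]]
    for (sys in setdiff(names(systems), "observed")) {
      met_hum <- template_metrics(templates[[paste(key, sys, sep = ".")]],
                                  obs_tpl, proto, normals)
      i <- which(vapply(rows, function(r)
        r$key == key && r$system == sys, logical(1)))
      rows[[i]]$mae_human <- met_hum$mae
      rows[[i]]$r_human <- met_hum$r_inout
    }
    write_ply(templates[[paste(key, "observed", sep = ".")]],
              file.path(out_dir, paste0("template_", key, ".ply")))
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$mae_human)) { r$mae_human <- NA_real_; r$r_human <- NA_real_ }
    r
  }))
  utils::write.table(tab, file.path(out_dir, "templates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  log_provenance(out_dir, "revcor", "templates", stage_seed(cfg, "revcor"))
  st$templates <- templates
  st$template_table <- tab
  st
}

run_stage_generalize <- function(cfg, out_dir, st) {
  gn <- cfg$generalization
  ex <- cfg$experiment
  model <- st$model
  V <- model$n_vertices
  # faithfulness matrix from observed-behavior templates vs permuted chance
  keys <- names(st$sessions)
  Fmat <- matrix(0L, V, length(keys))
  target_of <- integer(length(keys))
  for (i in seq_along(keys)) {
    key <- keys[i]
    t_id <- as.integer(sub(".*_t", "", key))
    target_of[i] <- t_id
    tg <- st$targets[[t_id]]
    proto <- gmf_prototype(tg$factors, model)
    normals <- vertex_normals(proto)
    ses <- st$sessions[[key]]$session
    chosen_comps <- attr(ses, "chosen_components")
    chosen_vert <- sweep(chosen_comps %*% (t(model$U_shape) * model$scale_shape),
                         2L, proto, "+")
    tpl <- st$templates[[paste(key, "observed", sep = ".")]]
    peak <- st$template_table$peak_amp[
      st$template_table$key == key & st$template_table$system == "observed"]
    set.seed(stage_seed(cfg, "generalization", i))
    chance <- rowMeans(vapply(seq_len(cfg$revcor$n_chance), function(p) {
      rf <- mass_univariate_fit(chosen_vert, sample(ses$rating))
      signed_normal_distance(rf$b0 + peak * rf$b1, proto, normals)
    }, numeric(V)))
    Fmat[, i] <- as.integer(classify_faithful(
      signed_normal_distance(tpl, proto, normals),
      chance,
      signed_normal_distance(tg$vertices, proto, normals)))
  }
  diag_comp <- diagnostic_components(Fmat, target_of, k = gn$k_nmf,
                                     loading_threshold = gn$loading_threshold,
                                     seed = stage_seed(cfg, "generalization"))
  targets <- lapply(seq_len(ex$n_targets), function(t)
    list(ground_truth = st$targets[[t]]$vertices,
         factors = st$targets[[t]]$factors,
         C_D = diag_comp[[as.character(t)]]$C_D))
  names(targets) <- paste0("t", seq_len(ex$n_targets))
  gset <- build_generalization_set(targets, model, amps = gn$amps)

  rows <- list()
  for (o in seq_len(ex$n_observers)) {
    responders <- lapply(seq_len(ex$n_targets), function(t) {
      key <- sprintf("o%02d_t%d", o, t)
      fold_mean_responder(st$fits[[key]]$shape, function(face)
        project_components(face, st$targets[[t]]$factors, model))
    })
    names(responders) <- paste0("t", seq_len(ex$n_targets))
    res <- suppressMessages(simulate_identification(responders, gset))
    # reference cohort: held-out noisy observers judging the same stimuli
    ref_acc <- rowMeans(vapply(seq_len(gn$n_validators), function(v) {
      set.seed(stage_seed(cfg, "generalization", o, v) + 7L)
      scores <- sapply(seq_len(ex$n_targets), function(t) {
        tg <- st$targets[[t]]
        apply(gset$faces, 1L, function(face) {
          comps <- project_components(face, tg$factors, model)
          -sum((comps - tg$components)^2)
        }) + stats::rnorm(nrow(gset$faces), sd = 1)
      })
      as.numeric(paste0("t", max.col(scores, ties.method = "first")) ==
                   gset$manifest$target)
    }, numeric(nrow(gset$faces))))
    err <- accuracy_error(res$accuracy, ref_acc)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(observer = o), res,
      data.frame(reference = ref_acc, abs_error = err$abs_error))
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(out_dir, "generalization.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_provenance(out_dir, "generalize", "generalization",
                 stage_seed(cfg, "generalization"))
  tab
}

#' Summarize a completed run
#'
#' Reads the stage artifacts of a run directory and writes four summary
#' tables (and, when `plots = TRUE`, matching figures): MI vs redundancy,
#' out-of-fold prediction performance, template veridicality/humanness, and
#' diagnostic vs non-diagnostic identification accuracy. Missing artifacts
#' are reported by name.
#'
#' @param run_dir run directory produced by [run_pipeline()].
#' @param plots also write PDF figures.
#' @return named list of summary data.frames.
#' @export
report <- function(run_dir, plots = TRUE) {
  need <- c("infotheory.tsv", "templates.tsv", "generalization.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0L)
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "))
  info <- utils::read.delim(file.path(run_dir, "infotheory.tsv"))
  tmpl <- utils::read.delim(file.path(run_dir, "templates.tsv"))
  gen <- utils::read.delim(file.path(run_dir, "generalization.tsv"))

  s_info <- stats::aggregate(cbind(mi_bits, redundancy_bits, exceeds) ~ space,
                             info, mean, na.action = stats::na.pass,
                             na.rm = TRUE)
  s_pred <- stats::aggregate(mi_bits ~ space + key, info, mean)
  s_tmpl <- stats::aggregate(cbind(mae_veridical, r_veridical, mae_human,
                                   r_human) ~ system, tmpl, mean,
                             na.action = stats::na.pass, na.rm = TRUE)
  gen$is_diag <- gen$diagnosticity == "diagnostic"
  s_gen <- stats::aggregate(accuracy ~ diagnosticity + alpha, gen, mean)

  tables <- list(info_summary = s_info, prediction_summary = s_pred,
                 template_summary = s_tmpl, generalization_summary = s_gen)
  for (nm in names(tables))
    utils::write.table(tables[[nm]],
                       file.path(run_dir, paste0("report_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (plots) {
    grDevices::pdf(file.path(run_dir, "report_figures.pdf"), width = 7,
                   height = 6)
    on.exit(grDevices::dev.off())
    plot(info$redundancy_bits, info$mi_bits, col = factor(info$space),
         xlab = "redundancy with shape predictions (bits)",
         ylab = "MI with behavior (bits)", main = "MI vs redundancy per fold")
    graphics::boxplot(mi_bits ~ space, info, ylab = "MI (bits)",
                      main = "Out-of-fold prediction information")
    plot(s_tmpl$r_veridical, s_tmpl$r_human,
         xlab = "veridicality r", ylab = "humanness r",
         main = "Template quality by system")
    graphics::text(s_tmpl$r_veridical, s_tmpl$r_human, s_tmpl$system,
                   pos = 3, cex = 0.8)
    acc_d <- s_gen$accuracy[s_gen$diagnosticity == "diagnostic"]
    acc_n <- s_gen$accuracy[s_gen$diagnosticity == "nondiagnostic"]
    alphas <- unique(s_gen$alpha)
    graphics::barplot(acc_d - acc_n, names.arg = alphas,
                      xlab = "amplification", ylab = "accuracy difference",
                      main = "Diagnostic - non-diagnostic accuracy")
  }
  invisible(tables)
}
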