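.pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, ddm = TRUE, decode = TRUE, stats = TRUE),
    simulate = list(
      n_subjects = 6L, trials_per_cell = 40L, target_accuracy = 0.71,
      confidence_format = "binary",
      n_channels = 32L, noise_scale = 1, times_ms_max = 5000,
      post_onset_ms = 2000, window_ms = 850
    ),
    ddm = list(
      models = c(1L, 4L, 7L, 10L),
      n_samples = 900L, n_burn = 400L, thin = 1L, chains = 2L
    ),
    decode = list(window_ms = 100, step_ms = 50, cost = 1,
                  tg_reps = 3L, tg_folds = 4L),
    stats = list(n_perm = 200L, cluster_alpha = 0.05, n_boot = 1000L)
  )
}

#' Build and validate a pipeline configuration
#'
#' Returns the default end-to-end configuration (a small synthetic study:
#' 6 subjects, 4 x 40 trials, 32 channels, reduced chain lengths and
#' permutation counts) with any supplied overrides merged in. Unknown keys
#' anywhere in the tree are rejected before any stage runs.
#'
#' @param ... Named overrides; nested lists merge recursively (e.g.
#'   `simulate = list(n_subjects = 8)`).
#' @param config Optional path to a YAML or JSON file of overrides.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., config = NULL) {
  overrides <- list(...)
  if (!is.null(config)) {
    file_cfg <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    overrides <- utils::modifyList(file_cfg, overrides)
  }
  merge_checked <- function(base, over, path = "") {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) {
      abort(paste0("unknown configuration key(s): ",
                   paste0(path, bad, collapse = ", ")))
    }
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_checked(base[[nm]], over[[nm]],
                                    paste0(path, nm, "."))
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  out <- merge_checked(.pipeline_defaults(), overrides)
  structure(out, class = "pipeline_config")
}

# deterministic per-stage seed expansion from the global seed
.stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + stage_index * 104729) %% 2147483647)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains all stages on synthetic data: session + epoch simulation, the
#' hierarchical diffusion fits with a DIC ladder over the configured models,
#' decision-variable decoding with temporal generalization, and the group
#' statistics (slope/intercept regressions, confidence-contrast cluster
#' permutation over subject TG matrices, mediation of the positive-evidence
#' effect on changes of mind by confidence). Artifacts are written to
#' `config$out_dir` when set; every stage's seed derives deterministically
#' from the global seed, so identical configurations give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: per-stage provenance (inputs, parameters, seed,
#'   duration), headline tables (DIC ladder, fixed effects, cluster p
#'   values), warnings, and a content checksum that excludes durations.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  headline <- list()
  warnings <- character(0)
  note <- function(stage, params, seed, t0) {
    stages[[stage]] <<- list(stage = stage, parameters = params, seed = seed,
                             duration_s = as.numeric(Sys.time()) - t0)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  trials <- NULL; epochs_sim <- NULL
  if (isTRUE(config$stages$simulate)) {
    t0 <- as.numeric(Sys.time()); sd1 <- .stage_seed(config$seed, 1L)
    sc <- config$simulate
    obs <- observer_spec()
    trials <- simulate_session(obs, n_subjects = sc$n_subjects,
                               trials_per_cell = sc$trials_per_cell,
                               target_accuracy = sc$target_accuracy,
                               confidence_format = sc$confidence_format,
                               seed = sd1)
    truth <- epoch_ground_truth(n_channels = sc$n_channels,
                                noise_scale = sc$noise_scale)
    epochs_sim <- purrr::map(unique(trials$subject_id), function(s) {
      tr <- dplyr::filter(trials, .data$subject_id == s)
      simulate_epochs(tr, truth, seed = sd1 + match(s, unique(trials$subject_id)),
                      times_ms = seq(0, sc$times_ms_max, by = 10),
                      post_onset_ms = sc$post_onset_ms,
                      window_ms = sc$window_ms)
    })
    if (!is.null(out_dir)) write_trials(trials, file.path(out_dir, "trials.csv"))
    note("simulate", sc, sd1, t0)
  }

  if (isTRUE(config$stages$ddm)) {
    if (is.null(trials)) abort("stage 'ddm' failed: no trial table (enable 'simulate')")
    t0 <- as.numeric(Sys.time()); sd2 <- .stage_seed(config$seed, 2L)
    dc <- config$ddm
    ladder <- purrr::map(dc$models, function(m) {
      fit <- fit_hierarchical(
        trials, build_model(m),
        fit_config(n_samples = dc$n_samples, n_burn = dc$n_burn,
                   thin = dc$thin, chains = dc$chains, seed = sd2 + m))
      if (!fit$converged) {
        warnings <<- c(warnings, sprintf("ddm model %d: convergence not established", m))
      }
      glance(fit)
    }) |> bind_rows()
    headline$dic_ladder <- arrange(ladder, .data$dic)
    if (!is.null(out_dir)) {
      readr::write_csv(headline$dic_ladder, file.path(out_dir, "dic_ladder.csv"))
    }
    note("ddm", dc, sd2, t0)
  }

  dv_tbl <- NULL; tg_list <- NULL
  if (isTRUE(config$stages$decode)) {
    if (is.null(epochs_sim)) abort("stage 'decode' failed: no epochs (enable 'simulate')")
    t0 <- as.numeric(Sys.time()); sd3 <- .stage_seed(config$seed, 3L)
    dcfg <- config$decode
    sc <- config$simulate
    per_subj <- purrr::imap(epochs_sim, function(es, i) {
      ep <- es$epochs
      pre <- sliding_features(crop_epochs(ep, 0, sc$window_ms, "pre_onset"),
                              window_ms = dcfg$window_ms, step_ms = dcfg$step_ms)
      post <- sliding_features(crop_epochs(ep, sc$post_onset_ms, sc$window_ms,
                                           "post_onset"),
                               window_ms = dcfg$window_ms, step_ms = dcfg$step_ms)
      ens <- train_decoders(pre, ep$trials$initial_choice, scheme = "loo",
                            cost = dcfg$cost)
      dv <- decode_dv(ens, post)
      tg <- temporal_generalization(pre, post, folds = dcfg$tg_folds,
                                    reps = dcfg$tg_reps, cost = dcfg$cost,
                                    seed = sd3 + i)
      list(dv = dv, tg = tg)
    })
    tg_list <- purrr::map(per_subj, "tg")
    peak <- peak_decodability(tg_list)
    dv_tbl <- purrr::map(per_subj, function(p) {
      unsign(dv_trend(p$dv, window_ms = c(0, as.numeric(peak))))
    }) |> bind_rows()
    headline$peak_ms <- as.numeric(peak)
    note("decode", dcfg, sd3, t0)
  }

  if (isTRUE(config$stages$stats)) {
    if (is.null(dv_tbl)) abort("stage 'stats' failed: no decoded DV (enable 'decode')")
    t0 <- as.numeric(Sys.time()); sd4 <- .stage_seed(config$seed, 4L)
    scfg <- config$stats
    headline$slope_effects <- slope_effects(dv_tbl)
    contrasts <- confidence_contrast(tg_list)
    cl <- cluster_permutation(contrasts, n_perm = scfg$n_perm,
                              cluster_alpha = scfg$cluster_alpha, seed = sd4)
    headline$clusters <- tidy(cl)
    med_dat <- trials |>
      mutate(pe = ifelse(.data$pe_condition == "HPE", 2, 1),
             pes = ifelse(.data$post_strength == "strong", 1, -1),
             acc_x_pes = .data$initial_correct * .data$pes)
    med <- mediation(med_dat, predictor = "pe",
                     mediator = "initial_confidence",
                     outcome = "change_of_mind",
                     covariates = c("initial_correct", "initial_rt", "pes",
                                    "acc_x_pes"),
                     n_boot = scfg$n_boot, seed = sd4 + 1L)
    headline$mediation <- tidy(med)
    if (!is.null(out_dir)) {
      readr::write_csv(headline$slope_effects,
                       file.path(out_dir, "slope_effects.csv"))
      readr::write_csv(headline$mediation, file.path(out_dir, "mediation.csv"))
    }
    note("stats", scfg, sd4, t0)
  }

  checksum <- digest::digest(headline, algo = "sha256")
  structure(list(stages = stages, headline = headline,
                 warnings = warnings, seed = config$seed,
                 checksum = checksum),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %s, checksum %s\n", x$seed,
              substr(x$checksum, 1, 12)))
  for (s in x$stages) {
    cat(sprintf("  stage %-9s seed %-11d %.1fs\n", s$stage, s$seed, s$duration_s))
  }
  if (!is.null(x$headline$dic_ladder)) {
    cat("  DIC ladder:\n"); print(x$headline$dic_ladder)
  }
  if (!is.null(x$headline$clusters)) {
    cat("  clusters:\n"); print(x$headline$clusters)
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
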