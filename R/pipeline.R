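# End-to-end orchestration: simulate -> fit -> compare -> behaviour -> RSA,
# with CSV/JSON artifacts and a run manifest.

#' Default pipeline configuration
#'
#' A complete, modest-sized configuration for [run_pipeline()]: an HGF
#' cohort on the default task design, fit by RW and HGF, random-effects
#' BMS, behavioural summaries, and an RSA stage on synthetic patterns.
#' Override any entry, or load a configuration from YAML/JSON with
#' [read_run_config()].
#'
#' @return Nested list of stage settings.
#' @export
default_run_config <- function() {
  list(
    task = list(n_runs = 3, blocks_per_run = 4, trials_per_block = 45,
                p_high = 0.7, reversal_window = c(20, 25), n_patterns = 8,
                phase_len = 10),
    agents = list(model = "hgf", n_subjects = 8,
                  params = list(zeta = 2, omega = NULL)),
    fitting = list(models = c("rw", "hgf"), n_restarts = 4),
    bms = list(alpha0 = 1, n_samples = 1e5),
    rsa = list(n_voxels = 60, stim_signal = 1, outcome_signal = 1,
               noise_sd = 1, epoch_pair = "LE-RE", n_perm = 1000),
    seed = 1)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Entries present in the file override the defaults from
#' [default_run_config()]; unknown top-level sections are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- default_run_config()
  extra <- setdiff(names(user), names(base))
  if (length(extra) > 0) {
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.simulators <- list(random = simulate_random, wsls = simulate_wsls,
                    rw = simulate_rw, hgf = simulate_hgf)

#' Simulate a cohort of agents on fresh task designs
#'
#' Each subject gets its own task design (child seed derived from `seed`)
#' and one simulated agent. For the RW and HGF models, a `NULL` perceptual
#' parameter (`alpha` / `omega`) is replaced by the Bayes-optimal value for
#' that subject's input sequence.
#'
#' @param model Agent model name.
#' @param n_subjects Cohort size.
#' @param config A [task_config()].
#' @param params Named list of simulator arguments (e.g. `zeta`, `omega`).
#' @param seed Master seed.
#' @return List with `trials` (row-bound trial tibble across subjects),
#'   `designs`, and `params_used` per subject.
#' @export
simulate_cohort <- function(model = c("hgf", "rw", "wsls", "random"),
                            n_subjects, config = task_config(),
                            params = list(), seed = 1) {
  model <- match.arg(model)
  designs <- lapply(seq_len(n_subjects), function(s) {
    generate_design(config, seed = seed * 1009 + s)
  })
  all_trials <- vector("list", n_subjects)
  params_used <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    p <- params
    if (model == "hgf" && is.null(p$omega)) {
      p$omega <- as.numeric(bayes_optimal_params("hgf", designs[[s]]))
    }
    if (model == "rw" && is.null(p$alpha)) {
      p$alpha <- as.numeric(bayes_optimal_params("rw", designs[[s]]))
    }
    args <- c(list(design = designs[[s]], seed = seed * 31 + s, subject = s), p)
    all_trials[[s]] <- do.call(.simulators[[model]], args)
    params_used[[s]] <- p
  }
  list(trials = do.call(rbind, all_trials), designs = designs,
       params_used = params_used)
}

#' Fit several models to every subject of a cohort
#'
#' @param trials Multi-subject trial tibble.
#' @param models Character vector of model names to fit.
#' @param n_restarts Restarts per fit.
#' @param seed RNG seed.
#' @return List with `table` (tibble: subject, model, parameter estimates
#'   as columns, `nll`, `lme`, `bic`) and `lme_matrix` (subjects x models).
#' @export
fit_cohort <- function(trials, models = c("rw", "hgf"), n_restarts = 4,
                       seed = 1) {
  subjects <- sort(unique(trials$subject))
  rows <- list()
  lme <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(subjects, models))
  for (si in seq_along(subjects)) {
    tr <- trials[trials$subject == subjects[si], ]
    for (m in models) {
      fit <- fit_map(m, tr, n_restarts = n_restarts, seed = seed + si)
      l <- laplace_lme(fit)
      lme[si, m] <- l
      est <- unlist(fit$estimates)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subjects[si], model = m,
        parameter = names(est), estimate = unname(est),
        nll = fit$nll, lme = l, bic = bic(fit))
    }
  }
  list(table = do.call(rbind, rows), lme_matrix = lme)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> model comparison -> behavioural summaries ->
#' RSA and writes one artifact per stage into `out_dir`: `trials.csv`,
#' `fits.csv`, `bms.json`, `behavior.csv` (plus `phase_tests.csv`),
#' `rsa.json`, and a `manifest.json` recording the seed, a hash of the
#' configuration, and the stage outputs. Any stage failure aborts with the
#' stage name; artifacts of completed stages are left in place.
#'
#' @param config Configuration list (see [default_run_config()]), or a path
#'   accepted by [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed %||% 1
  if (!config$agents$model %in% names(.simulators)) {
    stop("agents$model must be one of ",
         paste(names(.simulators), collapse = ", "), " (got '",
         config$agents$model, "')", call. = FALSE)
  }
  bad <- setdiff(config$fitting$models, c("random", "wsls", "rw", "hgf"))
  if (length(bad) > 0) {
    stop("fitting$models contains unknown model(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  task_cfg <- do.call(task_config, config$task)

  sim <- stage("simulate", {
    simulate_cohort(config$agents$model, config$agents$n_subjects,
                    config = task_cfg, params = config$agents$params,
                    seed = seed)
  })
  trials_path <- file.path(out_dir, "trials.csv")
  write_trajectory_csv(sim$trials, trials_path)
  outputs <- c(outputs, trials_path)

  fits <- stage("fit", {
    fit_cohort(sim$trials, models = config$fitting$models,
               n_restarts = config$fitting$n_restarts, seed = seed)
  })
  fits_path <- file.path(out_dir, "fits.csv")
  write.csv(as.data.frame(fits$table), fits_path, row.names = FALSE)
  outputs <- c(outputs, fits_path)

  bms <- stage("bms", {
    rfx_bms(fits$lme_matrix, alpha0 = config$bms$alpha0,
            n_samples = config$bms$n_samples, seed = seed)
  })
  bms_path <- file.path(out_dir, "bms.json")
  jsonlite::write_json(list(alpha = as.list(bms$alpha), r = as.list(bms$r),
                            xp = as.list(bms$xp), seed = seed),
                       bms_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, bms_path)

  behavior <- stage("behavior", {
    acc <- proportion_correct_by_phase(sim$trials)
    list(phase_accuracy = acc,
         phase_tests = compare_phases(acc),
         p_staying = p_staying(sim$trials))
  })
  behavior_path <- file.path(out_dir, "behavior.csv")
  write.csv(as.data.frame(behavior$phase_accuracy), behavior_path,
            row.names = FALSE)
  write.csv(as.data.frame(behavior$phase_tests),
            file.path(out_dir, "phase_tests.csv"), row.names = FALSE)
  outputs <- c(outputs, behavior_path)

  rsa <- stage("rsa", {
    pats <- synth_patterns(config$agents$n_subjects,
                           n_voxels = config$rsa$n_voxels,
                           stim_signal = config$rsa$stim_signal,
                           outcome_signal = config$rsa$outcome_signal,
                           noise_sd = config$rsa$noise_sd,
                           epoch_pair = config$rsa$epoch_pair,
                           seed = seed)
    rdms <- lapply(pats, function(p) empirical_rdm(p$pre, p$post))
    lapply(c(stimulus = "stimulus", outcome = "outcome"), function(sel) {
      res <- group_inference(rdms, model_rdm(sel),
                             n_perm = config$rsa$n_perm, seed = seed)
      list(effect_size = res$effect_size,
           p_signed_rank = res$p_signed_rank,
           p_permutation = res$p_permutation,
           n_perm = res$n_perm)
    })
  })
  rsa_path <- file.path(out_dir, "rsa.json")
  jsonlite::write_json(rsa, rsa_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, rsa_path)

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   outputs = basename(outputs))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(sim = sim, fits = fits, bms = bms, behavior = behavior,
                 rsa = rsa, manifest = manifest))
}
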