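# Pipeline orchestration: simulate -> segment -> kinematics -> kernel ->
# fit -> compare -> report, with deterministic seeding and a manifest.

#' Run configuration
#'
#' Assembles everything one reproducible analysis run needs.  Serialised as
#' JSON (see [read_run_config()]).
#'
#' @param conditions stimulation probabilities, one cohort per condition.
#' @param n_flies flies per condition.
#' @param n_trials trials per simulated fly (trial-level mode).
#' @param agent an [agent_spec] describing the simulated flies.
#' @param arena an [arena_config].
#' @param mode `"trial"` (trial-level agent simulation, default) or
#'   `"trajectory"` (full virtual-arena sessions segmented into trials).
#' @param duration session duration (s) in trajectory mode.
#' @param m regression history depth.
#' @param min_trials exclusion threshold for short sessions.
#' @param truncate_minutes value analyses use at most this much session time
#'   (default 30, trajectory mode).
#' @param models RL models to fit.
#' @param n_init random initialisations per fit.
#' @param generative_n_seq,generative_n_trials generative-test scale.
#' @param seed master seed; all stage/fly seeds derive from it.
#' @param outdir output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(conditions = c(0.05, 0.15, 0.3),
                       n_flies = 10, n_trials = 200,
                       agent = agent_spec("rl",
                                          rl_params("FQ", alpha = 0.4,
                                                    beta = 6, bias = 0.4)),
                       arena = arena_config(),
                       mode = c("trial", "trajectory"),
                       duration = 600, m = 10, min_trials = 50,
                       truncate_minutes = 30,
                       models = c("RW", "FQ", "FQaF"),
                       n_init = 100, generative_n_seq = 100,
                       generative_n_trials = 500,
                       seed = 1, outdir = tempfile("foragefly_run_")) {
  mode <- match.arg(mode)
  stopifnot(inherits(agent, "agent_spec"), inherits(arena, "arena_config"))
  for (p in conditions) stopifnot_prob(p, "condition")
  structure(list(conditions = conditions, n_flies = n_flies,
                 n_trials = n_trials, agent = agent, arena = arena,
                 mode = mode, duration = duration, m = m,
                 min_trials = min_trials,
                 truncate_minutes = truncate_minutes, models = models,
                 n_init = n_init, generative_n_seq = generative_n_seq,
                 generative_n_trials = generative_n_trials, seed = seed,
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] fields;
#'   `agent` is given as `{kind, alpha, beta, bias, alpha_f, q0,
#'   response_prob}` and `arena` as its field list.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  agent <- if (!is.null(j$agent)) {
    a <- j$agent
    if (identical(a$kind, "rl")) {
      agent_spec("rl", rl_params(a$model %||% "FQ", alpha = a$alpha,
                                 beta = a$beta, bias = a$bias,
                                 alpha_f = a$alpha_f, q0 = a$q0 %||% 0))
    } else {
      agent_spec(a$kind, response_prob = a$response_prob %||% 0.5)
    }
  } else NULL
  arena <- if (!is.null(j$arena)) do.call(arena_config, j$arena) else NULL
  args <- j[setdiff(names(j), c("agent", "arena"))]
  if (!is.null(agent)) args$agent <- agent
  if (!is.null(arena)) args$arena <- arena
  do.call(run_config, args)
}

#' Write a run configuration to JSON
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  j <- unclass(config)
  a <- config$agent
  j$agent <- c(list(kind = a$kind, response_prob = a$response_prob),
               if (a$kind == "rl") {
                 p <- a$rl_params
                 list(model = p$model, alpha = p$alpha, beta = p$beta,
                      bias = p$bias, alpha_f = p$alpha_f, q0 = p$q0)
               })
  j$arena <- unclass(config$arena)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, per condition and fly: simulation (trial-level agents or full
#' virtual-arena sessions segmented into trials), the minimum-trial filter,
#' reward-history regression, RL model fitting with AIC selection and
#' predictive F1, a population kernel, a generative test at the fitted
#' population-median FQ parameters, and (trajectory mode) kinematics.  Every
#' intermediate table is written under `config$outdir` and listed, with its
#' MD5 checksum, in `manifest.json`; re-running the same configuration
#' reproduces all outputs bit-identically.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "segment", "kinematics", "kernel", "fit", "compare",
#'   "report")` or `"all"`.
#' @return the report list, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "segment", "kinematics", "kernel", "fit",
                  "compare", "report")
  if (identical(stages, "all")) stages <- all_stages
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("foragefly")),
    seed = config$seed, stages = stages, status = "running")
  seqs_by_cond <- list()
  kin_rows <- NULL
  trial_files <- character(0)

  # --- simulate (and segment, in trajectory mode) ------------------------
  for (ci in seq_along(config$conditions)) {
    p <- config$conditions[ci]
    key <- sprintf("p%03d", round(p * 100))
    cond_seqs <- list()
    for (f in seq_len(config$n_flies)) {
      fseed <- derive_seed(config$seed, ci, f, "simulate")
      if (config$mode == "trial") {
        cs <- simulate_choice_sequence(config$agent, p, config$n_trials,
                                       fseed)
        cs$fly <- sprintf("%s_fly%02d", key, f)
      } else {
        arena <- config$arena
        arena$stim_probability_zone1 <- p
        session <- simulate_session_trajectory(arena, config$agent,
                                               config$duration, fseed)
        traj <- preprocess_trajectory(session)
        trials <- segment_trials(session)
        trunc <- config$truncate_minutes * 60
        trials <- trials[trials$t_enter_reward <= trunc, , drop = FALSE]
        flt <- filter_sessions(trials, config$min_trials)
        if ("segment" %in% stages) {
          tf <- file.path(outdir, sprintf("trials_%s_fly%02d.csv", key, f))
          write.csv(trials, tf, row.names = FALSE)
          trial_files <- c(trial_files, tf)
        }
        if ("kinematics" %in% stages) {
          ks <- kinematics_summary(traj, arena, trials)
          kin_rows <- rbind(kin_rows, data.frame(
            condition = p, fly = f, pi = ks$pi,
            dwell_zone1 = ks$zone_occupancy[["zone1"]],
            dwell_zone2 = ks$zone_occupancy[["zone2"]],
            n_trials = nrow(trials), excluded = flt$excluded))
        }
        if (flt$excluded) next
        cs <- trials_to_choice_sequence(trials, zone = 1L, p_reward = p,
                                        fly = sprintf("%s_fly%02d", key, f))
      }
      cond_seqs[[length(cond_seqs) + 1L]] <- cs
      if ("simulate" %in% stages) {
        write_choice_sequence_csv(
          cs, file.path(outdir, sprintf("choices_%s_fly%02d.csv", key, f)))
      }
    }
    seqs_by_cond[[key]] <- cond_seqs
  }
  if (!is.null(kin_rows)) {
    write.csv(kin_rows, file.path(outdir, "kinematics.csv"),
              row.names = FALSE)
  }

  # --- kernel ------------------------------------------------------------
  kernel_tab <- NULL
  if ("kernel" %in% stages) {
    spec <- regression_spec(m = config$m)
    for (key in names(seqs_by_cond)) {
      fits <- list()
      for (cs in seqs_by_cond[[key]]) {
        if (length(cs) <= config$m + 5) next
        res <- tryCatch(fit_logistic(build_history_design(cs, spec)),
                        error = function(e) NULL)
        if (!is.null(res)) fits[[length(fits) + 1L]] <- res
      }
      if (length(fits) >= 2) {
        pk <- population_kernel(fits)
        pk$condition <- key
        kernel_tab <- rbind(kernel_tab, pk)
      }
    }
    if (!is.null(kernel_tab)) {
      write.csv(kernel_tab, file.path(outdir, "kernel.csv"),
                row.names = FALSE)
    }
  }

  # --- fit / compare -----------------------------------------------------
  fit_tab <- NULL
  selection_counts <- NULL
  if (any(c("fit", "compare") %in% stages)) {
    for (key in names(seqs_by_cond)) {
      for (cs in seqs_by_cond[[key]]) {
        if (length(cs) < 20) next
        sc <- fit_and_score(cs, models = config$models,
                            n_init = config$n_init,
                            seed = derive_seed(config$seed, key,
                                               cs$fly %||% "fly", "fit"))
        for (m in config$models) {
          ft <- sc$fits[[m]]
          fit_tab <- rbind(fit_tab, data.frame(
            condition = key, fly = cs$fly, model = m,
            alpha = ft$params$alpha %||% NA_real_,
            beta = ft$params$beta %||% NA_real_,
            bias = ft$params$bias %||% NA_real_,
            alpha_f = ft$params$alpha_f %||% NA_real_,
            logL_mean = ft$logL_mean, AIC = ft$AIC, f1 = sc$f1[[m]],
            winner = sc$selection$winner == m))
        }
      }
    }
    if (!is.null(fit_tab)) {
      write.csv(fit_tab, file.path(outdir, "fits.csv"), row.names = FALSE)
      selection_counts <- as.data.frame(
        table(model = fit_tab$model[fit_tab$winner]),
        responseName = "n_flies_won")
      write.csv(selection_counts, file.path(outdir, "model_selection.csv"),
                row.names = FALSE)
    }
  }

  # --- generative comparison --------------------------------------------
  gen <- NULL
  if ("compare" %in% stages && !is.null(fit_tab)) {
    fq <- fit_tab[fit_tab$model == "FQ" & is.finite(fit_tab$alpha), ]
    if (nrow(fq) > 0) {
      med <- rl_params("FQ", alpha = median(fq$alpha),
                       beta = median(fq$beta), bias = median(fq$bias))
      gen <- generative_test(med, config$conditions,
                             n_seq = config$generative_n_seq,
                             n_trials = config$generative_n_trials,
                             seed = derive_seed(config$seed, "generative"))
      write.csv(gen$summary, file.path(outdir, "generative_summary.csv"),
                row.names = FALSE)
      write.csv(gen$run_lengths, file.path(outdir,
                                           "generative_run_lengths.csv"),
                row.names = FALSE)
    }
  }

  report <- list(
    conditions = config$conditions,
    n_flies = config$n_flies,
    n_sequences = vapply(seqs_by_cond, length, integer(1)),
    return_rate = lapply(seqs_by_cond, function(ss) {
      if (!length(ss)) return(NA_real_)
      mean(vapply(ss, function(s) mean(s$choices), numeric(1)))
    }),
    reward_rate = lapply(seqs_by_cond, function(ss) {
      if (!length(ss)) return(NA_real_)
      mean(vapply(ss, function(s) mean(s$rewards), numeric(1)))
    }),
    kinematics = if (!is.null(kin_rows)) kin_rows else NULL,
    kernel = kernel_tab,
    fits = fit_tab,
    model_selection = selection_counts,
    generative = if (!is.null(gen)) gen$summary else NULL)

  if ("report" %in% stages) write_report(report, outdir)

  files <- list.files(outdir, full.names = TRUE, recursive = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$status <- "complete"
  manifest$config_hash <- digest_config(config)
  manifest$files <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

digest_config <- function(config) {
  j <- config
  j$outdir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(j), auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write the human- and machine-readable report
#'
#' @param report the report list produced by [run_pipeline()].
#' @param outdir output directory.
#' @return paths written, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", force = TRUE)
  txt <- c("foragefly pipeline report", "=========================", "")
  for (i in seq_along(report$n_sequences)) {
    key <- names(report$n_sequences)[i]
    txt <- c(txt, sprintf(
      "condition %s: %d sequences, reward rate %.3f, return rate %.3f",
      key, report$n_sequences[[i]],
      report$reward_rate[[key]] %||% NA,
      report$return_rate[[key]] %||% NA))
  }
  if (!is.null(report$model_selection)) {
    txt <- c(txt, "", "model selection (flies won):",
             utils::capture.output(print(report$model_selection)))
  }
  if (!is.null(report$generative)) {
    txt <- c(txt, "", "generative test (population-median FQ):",
             utils::capture.output(print(report$generative, digits = 3)))
  }
  txt_path <- file.path(outdir, "report.txt")
  writeLines(txt, txt_path)
  invisible(c(json_path, txt_path))
}
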