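#' Read and validate a pipeline run configuration
#'
#' Loads a YAML configuration and merges it over the package defaults.
#' A run is reproducible from its configuration alone: every command
#' logs the configuration's MD5 hash and the seeds in use.
#'
#' Sections (all optional; defaults shown by `default_run_config()`):
#' `game` (`N`, `T`, `E`, `c`, `R`), `cohort` (`n_subjects`, `n_blocks`,
#' `model`, `k_levels`, `seed`), `fitting` (`models`, `n_restarts`,
#' `seed`), `validate` (`n_subjects`, `n_replicates`, `seed`) and
#' `output_dir`.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A validated configuration list of class `pgg_run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(game = list(N = 5, T = 15, E = 1, c = 1, R = 2),
       cohort = list(n_subjects = 25, n_blocks = 12, model = "sl",
                     k_levels = c(2, 4), seed = 1),
       fitting = list(models = c("sl", "myopic", "gu", "ia"),
                      n_restarts = 10, seed = 1),
       validate = list(n_subjects = 6, n_replicates = 3, seed = 1),
       output_dir = "pggsl-out")
}

validate_run_config <- function(cfg) {
  game <- do.call(pgg_config, c(cfg$game, k = cfg$cohort$k_levels[1]))
  if (!cfg$cohort$model %in% PGG_MODELS) {
    stop("cohort$model must be one of: ", paste(PGG_MODELS, collapse = ", "))
  }
  if (!all(cfg$fitting$models %in% PGG_MODELS)) {
    stop("fitting$models contains unknown model names")
  }
  stopifnot(cfg$cohort$n_subjects >= 0, cfg$cohort$n_blocks >= 1,
            cfg$fitting$n_restarts >= 1)
  cfg$game_config <- game
  class(cfg) <- "pgg_run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg[setdiff(names(cfg), "game_config")]), tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(...) message(sprintf(...))

#' Pipeline commands
#'
#' Thin, scriptable entry points tying the package together; each writes
#' delimited-text outputs under `config$output_dir` and logs the
#' configuration hash and seed. `run_simulate()` writes a synthetic
#' cohort and its ground-truth sidecar; `run_fit()` fits the configured
#' models to a data directory and writes per-subject fit and group
#' comparison tables; `run_regressors()` fits the social learning model
#' per subject and writes one model-based regressor table per subject;
#' `run_validate()` runs a scaled-down recovery report (parameter
#' recovery, model recovery, leave-one-block-out cross-validation,
#' ablation, and the model-free signature) sized by `config$validate`.
#'
#' @param config A `pgg_run_config` from [read_run_config()].
#' @param data_dir Directory with `trials.tsv` / `subjects.tsv` (defaults
#'   to the simulate output under `output_dir`).
#' @return Invisibly, the paths (or result objects) produced.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  log_msg("simulate: config %s, seed %d", config_hash(config),
          config$cohort$seed)
  spec <- cohort_spec(n_subjects = config$cohort$n_subjects,
                      n_blocks = config$cohort$n_blocks,
                      model = config$cohort$model,
                      cfg = config$game_config,
                      k_levels = config$cohort$k_levels,
                      seed = config$cohort$seed)
  cohort <- simulate_cohort(spec)
  dir <- file.path(config$output_dir, "data")
  paths <- write_cohort(cohort, dir)
  log_msg("simulate: wrote %d sessions under %s", length(cohort$sessions), dir)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_fit <- function(config, data_dir = file.path(config$output_dir, "data")) {
  log_msg("fit: config %s, seed %d", config_hash(config),
          config$fitting$seed)
  sessions <- read_sessions(data_dir, config$game_config)
  res <- fit_cohort(sessions, config$fitting$models,
                    n_restarts = config$fitting$n_restarts,
                    seed = config$fitting$seed)
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir, recursive = TRUE)
  fit_path <- file.path(config$output_dir, "fits.tsv")
  est <- do.call(rbind, lapply(names(res$fits), function(id) {
    do.call(rbind, lapply(names(res$fits[[id]]), function(m) {
      f <- res$fits[[id]][[m]]
      data.frame(subject = id, model = m,
                 parameter = names(f$estimate),
                 estimate = unname(f$estimate))
    }))
  }))
  write_table_meta(res$table, fit_path, config)
  write_table_meta(est, file.path(config$output_dir, "estimates.tsv"), config)
  cmp <- compare_models(res$table, seed = config$fitting$seed)
  cmp_df <- data.frame(model = names(cmp$summed_bic),
                       summed_bic = unname(cmp$summed_bic),
                       best_count = as.integer(cmp$best_counts),
                       model_freq = unname(cmp$model_freq),
                       exceedance = unname(cmp$exceedance))
  write_table_meta(cmp_df, file.path(config$output_dir, "comparison.tsv"),
                   config)
  log_msg("fit: best model by summed BIC: %s", cmp$best_model)
  invisible(list(fits = res, comparison = cmp))
}

#' @rdname pipeline
#' @export
run_regressors <- function(config,
                           data_dir = file.path(config$output_dir, "data")) {
  log_msg("regressors: config %s, seed %d", config_hash(config),
          config$fitting$seed)
  sessions <- read_sessions(data_dir, config$game_config)
  dir <- file.path(config$output_dir, "regressors")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sessions, function(s) {
    fit <- fit_mle("sl", s, n_restarts = config$fitting$n_restarts,
                   seed = config$fitting$seed)
    reg <- build_regressors(s, fit$estimate)
    p <- file.path(dir, paste0("regressors_", s$subject_id, ".tsv"))
    write_table_meta(reg, p, config)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_validate <- function(config) {
  v <- config$validate
  log_msg("validate: config %s, seed %d (n_subjects = %d, n_replicates = %d)",
          config_hash(config), v$seed, v$n_subjects, v$n_replicates)
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir, recursive = TRUE)
  nr <- config$fitting$n_restarts

  # parameter recovery on one generated cohort
  cohort <- simulate_cohort(cohort_spec(n_subjects = v$n_subjects,
                                        cfg = config$game_config,
                                        seed = v$seed))
  fits <- lapply(seq_along(cohort$sessions), function(j) {
    fit_mle("sl", cohort$sessions[[j]], n_restarts = nr, seed = v$seed + j)
  })
  est <- do.call(rbind, lapply(fits, function(f) as.data.frame(t(f$estimate))))
  truth <- cohort$ground_truth
  recovery <- do.call(rbind, lapply(model_par_names("sl"), function(p) {
    data.frame(parameter = p, mean_true = mean(truth[[p]]),
               mean_recovered = mean(est[[p]]),
               correlation = suppressWarnings(cor(truth[[p]], est[[p]])))
  }))
  write_table_meta(recovery,
                   file.path(config$output_dir, "parameter_recovery.tsv"),
                   config)

  # model recovery across replicates
  mr <- do.call(rbind, lapply(config$fitting$models, function(gen) {
    wins <- vapply(seq_len(v$n_replicates), function(r) {
      co <- simulate_cohort(cohort_spec(n_subjects = v$n_subjects,
                                        model = gen,
                                        cfg = config$game_config,
                                        seed = v$seed + 97L * r))
      tab <- fit_cohort(co$sessions, config$fitting$models,
                        n_restarts = nr, seed = v$seed + r)$table
      summed <- tapply(tab$bic, tab$model, sum)
      names(which.min(summed)) == gen
    }, logical(1))
    data.frame(generator = gen, n_replicates = v$n_replicates,
               recovered = sum(wins))
  }))
  write_table_meta(mr, file.path(config$output_dir, "model_recovery.tsv"),
                   config)

  # cross-validation and ablation on the first subject
  s1 <- cohort$sessions[[1]]
  cv <- loo_block_cv("sl", s1, n_restarts = max(3, nr %/% 2), seed = v$seed)
  write_table_meta(cv, file.path(config$output_dir, "loo_cv.tsv"), config)
  abl <- do.call(rbind, lapply(c("alpha", "theta", "lambda", "pi"),
                               function(w) {
    a <- ablate_sl(s1, w, n_restarts = nr, seed = v$seed)
    data.frame(removed = w, delta_bic = a$delta_bic,
               delta_lnL = a$delta_lnL)
  }))
  write_table_meta(abl, file.path(config$output_dir, "ablation.tsv"), config)

  # model-free signature on the generated cohort
  mf <- fit_subject_then_group(cohort$sessions)
  write_table_meta(mf$group, file.path(config$output_dir, "model_free.tsv"),
                   config)

  invisible(list(recovery = recovery, model_recovery = mr, cv = cv,
                 ablation = abl, model_free = mf$group))
}

# delimited output with a commented metadata header (seed, restarts, hash)
write_table_meta <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pggsl config=%s fit_seed=%s restarts=%s",
                     config_hash(config), config$fitting$seed,
                     config$fitting$n_restarts), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
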