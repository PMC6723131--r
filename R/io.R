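#' Read a phenotype table
#'
#' CSV with header; required columns `GID` and `ENV`, plus one numeric
#' column per trait. Missing trait values are preserved. Each line must
#' appear exactly once.
#'
#' @param path CSV path.
#' @return Data frame with character `GID`, `ENV` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("GID", "ENV") %in% names(df))) {
    stop("phenotype file must have columns GID and ENV: ", path)
  }
  df$GID <- as.character(df$GID)
  df$ENV <- as.character(df$ENV)
  dup <- which(duplicated(df$GID))
  if (length(dup) > 0) {
    stop("duplicate GID '", df$GID[dup[1]], "' (line ", dup[1] + 1L,
         "): lines must be observed exactly once")
  }
  traits <- setdiff(names(df), c("GID", "ENV"))
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) {
      v <- suppressWarnings(as.numeric(df[[tr]]))
      bad <- which(is.na(v) & !is.na(df[[tr]]) & df[[tr]] != "")
      if (length(bad) > 0) {
        stop("non-numeric value '", df[[tr]][bad[1]], "' for trait ", tr,
             " (line ", bad[1] + 1L, ")")
      }
      df[[tr]] <- v
    }
  }
  df
}

#' Write a phenotype table
#'
#' @param pheno Data frame with `GID`, `ENV` and trait columns.
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(path, config) {
  meta <- list(
    config_hash = config_hash(config),
    package = "kernpred",
    version = as.character(utils::packageVersion("kernpred")),
    config = config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

log_stage <- function(log_con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
  invisible(NULL)
}

#' Run a configured pipeline stage
#'
#' Orchestrates the package end to end from a structured configuration (a
#' named list, or a path to a YAML file with the same keys). Stages:
#' * `"simulate"` — generate a breeding dataset and write phenotype CSV,
#'   pedigree CSV, marker TSV and a JSON of the true components;
#' * `"fit"` — fit one model on the full data and write variance components
#'   (JSON) and per-observation predictions (CSV);
#' * `"cv1"` / `"v00"` — run a validation scheme and write per-environment
#'   results (CSV) and a JSON summary.
#'
#' Every output file gets a `.meta.json` sidecar carrying the configuration
#' and its hash; all randomness flows from `config$seed`. Identical
#' configurations produce identical output files.
#'
#' @param config Named list or YAML path. Common keys: `stage`, `out_dir`,
#'   `seed`, `trait`, `model`, input paths (`phenotypes`, `pedigree`,
#'   `markers`), `gibbs` (list: `n_iter`, `burn_in`, `thin`, `prior_df`,
#'   `prior_R2`), `cv` (list: `k`, `n_reps`), and for `simulate` a `sim`
#'   list passed to [simulate_breeding()].
#' @return (Invisibly) the list of files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$stage))
  stage <- match.arg(config$stage, c("simulate", "fit", "cv1", "v00"))
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log_path <- file.path(out_dir, paste0(stage, ".log"))
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  written <- character(0)
  emit <- function(path) {
    write_sidecar(path, config)
    written <<- c(written, path)
    path
  }

  if (stage == "simulate") {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    log_stage(log_con, "simulate: seed ", seed)
    sim <- do.call(simulate_breeding, sim_args)
    emit(write_phenotypes(sim$pheno, file.path(out_dir, "phenotypes.csv")))
    emit(write_pedigree(sim$pedigree, file.path(out_dir, "pedigree.csv")))
    if (!is.null(sim$markers)) {
      emit(write_markers(sim$markers, file.path(out_dir, "markers.tsv")))
    }
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(variance_fractions = as.list(sim$truth$variance_fractions),
           realized_fractions = as.list(sim$truth$realized_fractions),
           mu = sim$truth$mu, total_var = sim$truth$total_var),
      truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(truth_path)
    log_stage(log_con, "simulate: ", nrow(sim$pheno), " lines written to ",
              out_dir)
    return(invisible(written))
  }

  # fitting stages share the data-assembly step
  trait <- config$trait %||% "y"
  model <- config$model %||% "M1"
  labels <- model_terms(model)
  need_A <- any(c("A", "AE", "GA", "GAE") %in% labels)
  need_G <- any(c("G", "GE", "GA", "GAE") %in% labels)
  if (is.null(config$phenotypes)) stop("config$phenotypes path is required")
  if (need_G && is.null(config$markers)) {
    stop("model ", model, " needs markers but config$markers is not set")
  }
  if (need_A && is.null(config$pedigree)) {
    stop("model ", model, " needs a pedigree but config$pedigree is not set")
  }
  log_stage(log_con, stage, ": reading inputs")
  pheno <- read_phenotypes(config$phenotypes)
  ped <- if (need_A) read_pedigree(config$pedigree) else NULL
  markers <- if (need_G) read_markers(config$markers) else NULL
  data <- kern_data(pheno, trait = trait, pedigree = ped, markers = markers)
  log_stage(log_con, stage, ": ", nrow(data$obs), " observations, model ",
            model, ", seed ", seed)
  g <- config$gibbs %||% list()
  gib <- list(n_iter = g$n_iter %||% 4000, burn_in = g$burn_in %||% 1000,
              thin = g$thin %||% 5, prior_df = g$prior_df %||% 5,
              prior_R2 = g$prior_R2 %||% 0.5)

  if (stage == "fit") {
    t0 <- proc.time()[3]
    fit <- fit_gibbs(data, model = model, n_iter = gib$n_iter,
                     burn_in = gib$burn_in, thin = gib$thin, seed = seed,
                     prior_df = gib$prior_df, prior_R2 = gib$prior_R2)
    log_stage(log_con, "fit: done in ", round(proc.time()[3] - t0, 1), " s")
    res_path <- file.path(out_dir, paste0("fit_", model, ".json"))
    jsonlite::write_json(
      list(model = model, trait = trait,
           mu_hat = fit$mu_hat,
           var_components = as.list(fit$var_components),
           resid_var = fit$resid_var,
           percent_table = as.list(fit$percent_table),
           mcmc = fit$mcmc_meta[c("seed", "n_iter", "burn_in", "thin",
                                  "retained")]),
      res_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit(res_path)
    pred_path <- file.path(out_dir, paste0("predictions_", model, ".csv"))
    utils::write.csv(data.frame(GID = fit$obs$gid, ENV = fit$obs$env,
                                observed = fit$y,
                                predicted = fit$predictions),
                     pred_path, row.names = FALSE, quote = FALSE)
    emit(pred_path)
  } else {
    cv <- config$cv %||% list()
    t0 <- proc.time()[3]
    res <- if (stage == "cv1") {
      run_cv1(data, model = model, k = cv$k %||% 5, n_reps = cv$n_reps %||% 20,
              seed = seed, n_iter = gib$n_iter, burn_in = gib$burn_in,
              thin = gib$thin, prior_df = gib$prior_df,
              prior_R2 = gib$prior_R2)
    } else {
      run_v00(data, model = model, seed = seed, n_iter = gib$n_iter,
              burn_in = gib$burn_in, thin = gib$thin,
              prior_df = gib$prior_df, prior_R2 = gib$prior_R2)
    }
    log_stage(log_con, stage, ": done in ", round(proc.time()[3] - t0, 1),
              " s; weighted mean r = ", round(res$weighted_mean["mean"], 4))
    csv_path <- file.path(out_dir, paste0(stage, "_", model, ".csv"))
    utils::write.csv(data.frame(env = rownames(res$per_env),
                                mean_r = res$per_env[, "mean"],
                                sd_r = res$per_env[, "sd"],
                                n = res$n_per_env[rownames(res$per_env)]),
                     csv_path, row.names = FALSE, quote = FALSE)
    emit(csv_path)
    json_path <- file.path(out_dir, paste0(stage, "_", model, "_summary.json"))
    jsonlite::write_json(
      list(scheme = res$scheme, model = model, trait = trait,
           weighted_mean = res$weighted_mean["mean"],
           weighted_sd = res$weighted_mean["sd"],
           replicates = res$replicates,
           n_per_env = as.list(res$n_per_env)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    emit(json_path)
  }
  invisible(written)
}
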