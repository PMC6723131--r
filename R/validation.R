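#' Pearson correlation with validation
#'
#' Product-moment correlation between observed and predicted values, with
#' the degenerate cases rejected explicitly so that callers decide the skip
#' policy.
#'
#' @param obs,pred Paired numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2) stop("need at least 2 paired points")
  if (anyNA(obs) || anyNA(pred)) stop("missing values in correlation input")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    stop("zero variance in correlation input")
  }
  stats::cor(obs, pred)
}

#' Weighted mean of per-environment correlations
#'
#' Each environment's correlation is weighted by its share of the total
#' observation count: `sum_e r_e * n_e / sum(n)`.
#'
#' @param per_env_r Named numeric vector of correlations.
#' @param n_per_env Named numeric vector of counts (same names).
#' @return The weighted mean.
#' @export
weighted_mean_corr <- function(per_env_r, n_per_env) {
  if (length(per_env_r) == 0) stop("empty correlation map")
  if (!setequal(names(per_env_r), names(n_per_env))) {
    stop("environment keys of correlations and counts differ")
  }
  n <- n_per_env[names(per_env_r)]
  if (any(n <= 0)) stop("non-positive environment count")
  sum(per_env_r * n) / sum(n)
}

#' CV1 fold partitions
#'
#' Per replicate, a seeded random permutation of the lines split into `k`
#' near-equal folds (sizes differ by at most 1, remainder assigned to the
#' earliest folds).
#'
#' @param gids Line identifiers.
#' @param k Number of folds.
#' @param n_reps Number of replicate partitions.
#' @param seed Master seed; replicate `i` uses `seed + i`.
#' @return List of length `n_reps`; each element is an integer fold label
#'   (1..k) named by line id.
#' @export
cv1_partitions <- function(gids, k = 5, n_reps = 20, seed = 1) {
  n <- length(gids)
  if (k > n) stop("k = ", k, " folds exceed ", n, " lines")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  lapply(seq_len(n_reps), function(i) {
    set.seed(as.integer(seed) + i)
    perm <- sample(gids)
    stats::setNames(rep(seq_len(k), sizes), perm)[gids]
  })
}

new_cv_result <- function(scheme, per_env, weighted, n_per_env, replicates,
                          model) {
  structure(list(scheme = scheme, model = model, per_env = per_env,
                 weighted_mean = weighted, n_per_env = n_per_env,
                 replicates = replicates),
            class = "kern_cv")
}

#' @export
print.kern_cv <- function(x, ...) {
  cat(x$scheme, "validation of", x$model,
      if (x$scheme == "CV1") paste0("(", x$replicates, " replicates)"), "\n")
  tab <- data.frame(env = rownames(x$per_env),
                    mean_r = round(x$per_env[, "mean"], 3),
                    sd_r = round(x$per_env[, "sd"], 3),
                    n = x$n_per_env[rownames(x$per_env)], row.names = NULL)
  print(tab, row.names = FALSE)
  cat(sprintf("weighted mean r: %.3f", x$weighted_mean["mean"]))
  if (is.finite(x$weighted_mean["sd"])) {
    cat(sprintf(" (sd %.3f)", x$weighted_mean["sd"]))
  }
  cat("\n")
  invisible(x)
}

score_by_env <- function(obs_df, preds, env_levels) {
  # per-env Pearson on a joined prediction vector; skip-and-warn policy
  r <- stats::setNames(rep(NA_real_, length(env_levels)), env_levels)
  for (ev in env_levels) {
    sel <- which(obs_df$env == ev & !is.na(obs_df$y))
    if (length(sel) < 2 || stats::sd(obs_df$y[sel]) == 0 ||
        stats::sd(preds[sel]) == 0) {
      warning("environment ", ev, " skipped: fewer than 2 scorable ",
              "observations or zero variance", call. = FALSE)
      next
    }
    r[ev] <- pearson(obs_df$y[sel], preds[sel])
  }
  r
}

#' Run the CV1 random cross-validation scheme
#'
#' For each replicate: partition the lines into `k` folds; for each fold,
#' hide the fold's phenotypes, refit, and collect the held-out predictions;
#' join the `k` test vectors and compute the Pearson correlation within each
#' environment; summarize per-environment and weighted-mean correlations
#' over replicates. Every held-out line is absent from training (lines are
#' observed once), so CV1 predicts lines never seen in any environment.
#'
#' @param data A [kern_data], or a prebuilt (optionally factorized)
#'   [kern_model] whose cached kernel bases are then reused across fits.
#' @param model Model name `"M1"`..`"M8"` (ignored when `data` is already a
#'   `kern_model`).
#' @param k,n_reps Folds and replicate count.
#' @param seed Master seed; fold fits use seeds derived from it.
#' @param n_iter,burn_in,thin,prior_df,prior_R2,eigen_tol Passed to
#'   [fit_gibbs()].
#' @return Object of class `"kern_cv"` with `per_env` (mean and sd of r over
#'   replicates), `weighted_mean` (mean and sd over replicates of the
#'   per-replicate weighted mean), `n_per_env`, and the per-replicate
#'   matrices in `attr(, "replicate_r")`.
#' @export
run_cv1 <- function(data, model = "M1", k = 5, n_reps = 20, seed = 1,
                    n_iter = 4000, burn_in = 1000, thin = 5, prior_df = 5,
                    prior_R2 = 0.5, eigen_tol = 1e-8) {
  model_obj <- if (inherits(data, "kern_model")) data else
    make_model(data, model)
  model <- model_obj$name
  model_obj <- factorize_model(model_obj, eigen_tol)
  obs <- model_obj$obs
  gids <- obs$gid[!is.na(obs$y)]
  parts <- cv1_partitions(gids, k = k, n_reps = n_reps, seed = seed)
  env_levels <- sort(unique(obs$env))
  rep_r <- matrix(NA_real_, n_reps, length(env_levels),
                  dimnames = list(NULL, env_levels))
  rep_wm <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    folds <- parts[[i]]
    preds <- stats::setNames(rep(NA_real_, nrow(obs)), obs$gid)
    for (f in seq_len(k)) {
      test_gids <- names(folds)[folds == f]
      fit <- fit_gibbs(model_obj, n_iter = n_iter, burn_in = burn_in,
                       thin = thin, seed = as.integer(seed) + 1000L * i + f,
                       prior_df = prior_df, prior_R2 = prior_R2,
                       eigen_tol = eigen_tol, mask = test_gids)
      preds[test_gids] <- fit$predictions[test_gids]
    }
    r <- score_by_env(obs, preds[obs$gid], env_levels)
    rep_r[i, ] <- r
    ok <- !is.na(r)
    nn <- table(obs$env[!is.na(obs$y)])[env_levels[ok]]
    rep_wm[i] <- weighted_mean_corr(r[ok], stats::setNames(as.numeric(nn),
                                                           env_levels[ok]))
  }
  per_env <- cbind(mean = colMeans(rep_r, na.rm = TRUE),
                   sd = apply(rep_r, 2, stats::sd, na.rm = TRUE))
  weighted <- c(mean = mean(rep_wm), sd = stats::sd(rep_wm))
  n_per_env <- stats::setNames(as.numeric(table(obs$env)[env_levels]), env_levels)
  out <- new_cv_result("CV1", per_env, weighted, n_per_env, n_reps, model)
  attr(out, "replicate_r") <- rep_r
  attr(out, "replicate_weighted") <- rep_wm
  out
}

#' Run the leave-one-year-out (V00) validation scheme
#'
#' For each environment (year), hide all of its phenotypes, refit on the
#' remaining years (the held-out rows stay in the model with missing
#' phenotypes), and correlate predictions with the held-out observations
#' within that year. Predicting a whole new year relies only on the genetic
#' main effects transmitted through relatives: the held-out year's
#' environment and interaction effects have prior mean 0. Run once — no
#' random partitioning is possible.
#'
#' @inheritParams run_cv1
#' @return Object of class `"kern_cv"`; `per_env` carries the single-run
#'   correlations (sd `NA`).
#' @export
run_v00 <- function(data, model = "M1", seed = 1, n_iter = 4000,
                    burn_in = 1000, thin = 5, prior_df = 5, prior_R2 = 0.5,
                    eigen_tol = 1e-8) {
  model_obj <- if (inherits(data, "kern_model")) data else
    make_model(data, model)
  model <- model_obj$name
  model_obj <- factorize_model(model_obj, eigen_tol)
  obs <- model_obj$obs
  env_levels <- sort(unique(obs$env))
  if (length(env_levels) < 2) stop("V00 needs at least 2 environments")
  r <- stats::setNames(rep(NA_real_, length(env_levels)), env_levels)
  for (j in seq_along(env_levels)) {
    ev <- env_levels[j]
    test_idx <- which(obs$env == ev)
    fit <- fit_gibbs(model_obj, n_iter = n_iter, burn_in = burn_in,
                     thin = thin, seed = as.integer(seed) + j,
                     prior_df = prior_df, prior_R2 = prior_R2,
                     eigen_tol = eigen_tol, mask = test_idx)
    sel <- test_idx[!is.na(obs$y[test_idx])]
    if (length(sel) < 2 || stats::sd(obs$y[sel]) == 0) {
      warning("environment ", ev, " skipped: fewer than 2 scorable ",
              "observations or zero variance", call. = FALSE)
      next
    }
    r[ev] <- pearson(obs$y[sel], fit$predictions[sel])
  }
  ok <- !is.na(r)
  n_per_env <- stats::setNames(as.numeric(table(obs$env)[env_levels]), env_levels)
  weighted <- c(mean = weighted_mean_corr(r[ok], n_per_env[ok]), sd = NA_real_)
  per_env <- cbind(mean = r, sd = NA_real_)
  new_cv_result("V00", per_env, weighted, n_per_env, 1L, model)
}
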