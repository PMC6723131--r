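#' Fit a multi-kernel Gaussian model by Gibbs sampling
#'
#' Fits `y = 1 mu + sum_k u_k + e` with `u_k ~ N(0, K_k sigma2_k)` and
#' `e ~ N(0, I sigma2)`. Each kernel is re-parameterized through its eigen
#' factorization `K = B B'` so that `u_k = B_k delta_k` with iid regression
#' coefficients `delta_k ~ N(0, I sigma2_k)`; because the columns of `B_k`
#' are orthogonal the full conditional of `delta_k` is diagonal and each
#' Gibbs update costs two matrix-vector products. Variance components get
#' scaled-inverse-chi-square full conditionals; the intercept has a flat
#' prior; missing phenotypes are imputed by data augmentation each
#' iteration, which is also how held-out observations are predicted in the
#' validation schemes.
#'
#' Priors: `sigma2_k ~ ScaledInvChiSq(df, S_k)` with
#' `S_k = var(y_obs) * prior_R2 / n_terms * (df + 2)` (prior mode
#' `var(y_obs) * prior_R2 / n_terms`), and the residual scale uses the
#' `1 - prior_R2` share.
#'
#' @param data A [kern_data] or prebuilt [kern_model] (the latter reuses
#'   cached kernel factorizations across fits).
#' @param model Model name `"M1"`..`"M8"` (ignored when `data` is already a
#'   `kern_model`).
#' @param n_iter,burn_in,thin MCMC length, burn-in, thinning (retained
#'   samples are iterations `burn_in + thin, burn_in + 2*thin, ...`).
#' @param seed Integer seed; chains are bit-reproducible given identical
#'   seed and configuration.
#' @param prior_df,prior_R2 Prior degrees of freedom and the prior share of
#'   phenotypic variance attributed to the random terms jointly.
#' @param eigen_tol Relative eigenvalue cutoff for kernel factorization.
#' @param mask Optional vector of line ids (or observation indices) whose
#'   phenotypes are hidden from the sampler and predicted; on top of any
#'   `NA` already present.
#' @param fix_variances Optional named numeric vector fixing the variance
#'   components (names = term labels, plus `"Res"` for the residual);
#'   fixed components are not sampled. Used for closed-form cross-checks.
#' @param verbose Print progress every 1000 iterations.
#' @return Object of class `"kern_fit"`; see [summary.kern_fit()],
#'   [predict.kern_fit()], [variance_percent()].
#' @export
fit_gibbs <- function(data, model = "M1", n_iter = 12000, burn_in = 2000,
                      thin = 5, seed = 1, prior_df = 5, prior_R2 = 0.5,
                      eigen_tol = 1e-8, mask = NULL, fix_variances = NULL,
                      verbose = FALSE) {
  if (inherits(data, "kern_data")) {
    model_obj <- make_model(data, model)
  } else if (inherits(data, "kern_model")) {
    model_obj <- data
  } else stop("data must be a kern_data or kern_model object")
  stopifnot(burn_in < n_iter, thin >= 1, prior_df > 0,
            prior_R2 > 0, prior_R2 < 1)
  model_obj <- factorize_model(model_obj, eigen_tol = eigen_tol)

  obs <- model_obj$obs
  n <- nrow(obs)
  y <- obs$y
  if (any(!is.finite(y) & !is.na(y))) stop("non-finite phenotype value")
  if (!is.null(mask)) {
    if (is.character(mask)) {
      y[obs$gid %in% mask] <- NA
    } else y[mask] <- NA
  }
  miss <- which(is.na(y))
  train <- which(!is.na(y))
  if (length(train) < 2) stop("need at least 2 non-missing phenotypes")
  if (stats::var(y[train]) < 1e-12) {
    stop("phenotype is constant on the training observations")
  }

  labels <- names(model_obj$terms)
  K <- length(labels)
  B <- lapply(model_obj$factors, `[[`, "B")
  d <- lapply(model_obj$factors, `[[`, "values")
  r <- vapply(B, ncol, 0L)

  vy <- stats::var(y[train])
  df0 <- prior_df
  Sk <- vy * prior_R2 / K * (df0 + 2)
  Se <- vy * (1 - prior_R2) * (df0 + 2)

  fixed <- rep(FALSE, K + 1)
  names(fixed) <- c(labels, "Res")
  s2 <- c(rep(vy * prior_R2 / K, K), vy * (1 - prior_R2))
  names(s2) <- c(labels, "Res")
  if (!is.null(fix_variances)) {
    bad <- setdiff(names(fix_variances), names(s2))
    if (length(bad) > 0) stop("fix_variances names not in model: ",
                              paste(bad, collapse = ", "))
    s2[names(fix_variances)] <- fix_variances
    fixed[names(fix_variances)] <- TRUE
  }

  set.seed(as.integer(seed))
  ystar <- y
  mu <- mean(y[train])
  ystar[miss] <- mu
  delta <- lapply(r, numeric)
  U <- matrix(0, n, K)

  n_keep <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, n_keep, K + 2,
                  dimnames = list(NULL, c("mu", labels, "Res")))
  eta_sum <- numeric(n)
  U_sum <- matrix(0, n, K, dimnames = list(NULL, labels))
  mu_sum <- 0
  kept <- 0L

  for (it in seq_len(n_iter)) {
    usum <- if (K > 0) rowSums(U) else numeric(n)
    # intercept, flat prior
    mu <- stats::rnorm(1, mean(ystar - usum), sqrt(s2["Res"] / n))
    # one term at a time: diagonal full conditional in the factor basis
    for (k in seq_len(K)) {
      rk <- ystar - mu - usum + U[, k]
      rhs <- crossprod(B[[k]], rk) / s2["Res"]
      cinv <- 1 / (d[[k]] / s2["Res"] + 1 / s2[k])
      dk <- cinv * rhs + sqrt(cinv) * stats::rnorm(r[k])
      delta[[k]] <- dk
      unew <- drop(B[[k]] %*% dk)
      usum <- usum - U[, k] + unew
      U[, k] <- unew
      if (!fixed[k]) {
        s2[k] <- (sum(dk^2) + Sk) / stats::rchisq(1, df0 + r[k])
      }
    }
    e <- ystar - mu - usum
    if (!fixed["Res"]) {
      s2["Res"] <- (sum(e^2) + Se) / stats::rchisq(1, df0 + n)
    }
    if (!all(is.finite(s2)) || s2["Res"] > 1e12 * vy) {
      stop("divergent variance component at iteration ", it)
    }
    if (length(miss) > 0) {
      eta_miss <- mu + usum[miss]
      ystar[miss] <- eta_miss + stats::rnorm(length(miss), 0, sqrt(s2["Res"]))
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- c(mu, s2)
      eta_sum <- eta_sum + mu + usum
      U_sum <- U_sum + U
      mu_sum <- mu_sum + mu
    }
    if (verbose && it %% 1000 == 0) {
      message("iteration ", it, " / ", n_iter)
    }
  }

  var_components <- colMeans(draws[, labels, drop = FALSE])
  resid_var <- mean(draws[, "Res"])
  predictions <- eta_sum / kept
  fit <- structure(list(
    model = model_obj$name,
    trait = model_obj$trait,
    obs = obs,
    y = y,
    masked = miss,
    mu_hat = mu_sum / kept,
    var_components = var_components,
    resid_var = resid_var,
    percent_table = NULL,
    predictions = stats::setNames(predictions, obs$gid),
    effect_means = U_sum / kept,
    samples = draws,
    mcmc_meta = list(seed = seed, n_iter = n_iter, burn_in = burn_in,
                     thin = thin, retained = kept, prior_df = prior_df,
                     prior_R2 = prior_R2, eigen_tol = eigen_tol,
                     ranks = r)),
    class = "kern_fit")
  fit$percent_table <- variance_percent(fit)
  fit
}

#' Percent of total variance per random effect
#'
#' `percent_k = 100 * sigma2_k / (sum_j sigma2_j + sigma2_res)`, including a
#' residual row; sums to 100 exactly as computed.
#'
#' @param fit A [kern_fit], or a named numeric vector of variance components
#'   that includes a `"Res"` element.
#' @return Named numeric vector of percentages.
#' @export
variance_percent <- function(fit) {
  v <- if (inherits(fit, "kern_fit")) {
    c(fit$var_components, Res = fit$resid_var)
  } else {
    stopifnot(is.numeric(fit), "Res" %in% names(fit))
    fit
  }
  100 * v / sum(v)
}

#' Closed-form BLUP at fixed variance components
#'
#' Solves the phenotypic mixed-model system `V = sum_k sigma2_k K_k +
#' sigma2 I` on the training observations, estimates the intercept by GLS,
#' and predicts every observation (including masked ones, via the kernel
#' cross-covariance rows): `u_hat_k = sigma2_k K_k[, train] V^-1 (y - mu)`.
#' Serves as the independent oracle for the Gibbs sampler run at fixed
#' variances.
#'
#' @param data A [kern_data] or [kern_model].
#' @param model Model name (when `data` is a `kern_data`).
#' @param variances Named vector of term variance components.
#' @param resid_var Residual variance.
#' @param mask As in [fit_gibbs()].
#' @return List with `mu_hat`, `predictions` (posterior mean of
#'   `mu + sum u_k` per observation), and per-term `effects`.
#' @export
blup_fixed_variances <- function(data, model = "M1", variances, resid_var,
                                 mask = NULL) {
  model_obj <- if (inherits(data, "kern_model")) data else make_model(data, model)
  obs <- model_obj$obs
  y <- obs$y
  if (!is.null(mask)) {
    if (is.character(mask)) y[obs$gid %in% mask] <- NA else y[mask] <- NA
  }
  train <- which(!is.na(y))
  labels <- names(model_obj$terms)
  stopifnot(all(labels %in% names(variances)), resid_var > 0)
  n <- nrow(obs)
  V <- diag(resid_var, length(train))
  for (lab in labels) {
    V <- V + variances[lab] * model_obj$terms[[lab]]$K[train, train]
  }
  ones <- rep(1, length(train))
  Vi_y <- solve(V, y[train])
  Vi_1 <- solve(V, ones)
  mu <- sum(ones * Vi_y) / sum(ones * Vi_1)
  alpha <- solve(V, y[train] - mu)
  effects <- matrix(0, n, length(labels), dimnames = list(obs$gid, labels))
  for (lab in labels) {
    effects[, lab] <- variances[lab] *
      drop(model_obj$terms[[lab]]$K[, train] %*% alpha)
  }
  preds <- mu + rowSums(effects)
  list(mu_hat = mu, predictions = stats::setNames(preds, obs$gid),
       effects = effects)
}

#' Bayesian ridge regression on marker covariates
#'
#' Explicit marker-effect sampler for `y = 1 mu + X b + e` with
#' `b_m ~ iid N(0, sigma2_b)`: the dual of the genomic-kernel model, since
#' `Cov(X b) = X X' sigma2_b = G * (p sigma2_b)`. Used as an independent
#' route to cross-check kernel fits (`sigma2_g = p * sigma2_b`). Coefficients
#' are drawn jointly each iteration through a precomputed eigen
#' decomposition of `X'X`.
#'
#' @param y Phenotype vector (no missing values).
#' @param X Standardized marker matrix (n x p).
#' @param n_iter,burn_in,thin,seed,prior_df,prior_R2 As in [fit_gibbs()];
#'   the prior scale for `sigma2_b` spreads the genetic share over the `p`
#'   markers.
#' @return List with `mu_hat`, `b_hat`, `predictions` (posterior mean of
#'   `mu + X b`), `sigma2_b`, `sigma2_g = p * sigma2_b`, `resid_var`.
#' @export
ridge_gibbs <- function(y, X, n_iter = 6000, burn_in = 1000, thin = 5,
                        seed = 1, prior_df = 5, prior_R2 = 0.5) {
  stopifnot(!anyNA(y), nrow(X) == length(y))
  n <- length(y); p <- ncol(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  Q <- eg$vectors
  lam <- pmax(eg$values, 0)
  XtyQ <- function(v) crossprod(Q, crossprod(X, v))  # Q' X' v

  vy <- stats::var(y)
  df0 <- prior_df
  Sb <- vy * prior_R2 / p * (df0 + 2)
  Se <- vy * (1 - prior_R2) * (df0 + 2)
  set.seed(as.integer(seed))
  mu <- mean(y)
  s2b <- vy * prior_R2 / p
  s2e <- vy * (1 - prior_R2)
  b <- numeric(p)
  Xb <- numeric(n)

  keep <- (n_iter - burn_in) %/% thin
  mu_sum <- 0; b_sum <- numeric(p); eta_sum <- numeric(n)
  s2b_sum <- 0; s2e_sum <- 0; kept <- 0L
  for (it in seq_len(n_iter)) {
    mu <- stats::rnorm(1, mean(y - Xb), sqrt(s2e / n))
    # joint draw of b in the eigenbasis of X'X
    cinv <- 1 / (lam / s2e + 1 / s2b)
    m <- cinv * drop(XtyQ(y - mu)) / s2e
    z <- m + sqrt(cinv) * stats::rnorm(p)
    b <- drop(Q %*% z)
    Xb <- drop(X %*% b)
    s2b <- (sum(b^2) + Sb) / stats::rchisq(1, df0 + p)
    e <- y - mu - Xb
    s2e <- (sum(e^2) + Se) / stats::rchisq(1, df0 + n)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      mu_sum <- mu_sum + mu
      b_sum <- b_sum + b
      eta_sum <- eta_sum + mu + Xb
      s2b_sum <- s2b_sum + s2b
      s2e_sum <- s2e_sum + s2e
    }
  }
  list(mu_hat = mu_sum / kept, b_hat = b_sum / kept,
       predictions = eta_sum / kept, sigma2_b = s2b_sum / kept,
       sigma2_g = p * s2b_sum / kept, resid_var = s2e_sum / kept,
       retained = kept)
}
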