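#' @export
print.kern_fit <- function(x, ...) {
  cat("Multi-kernel Gibbs fit:", x$model, "on trait", x$trait, "\n")
  cat("  ", nrow(x$obs), " observations (", length(x$masked),
      " masked), ", x$mcmc_meta$retained, " retained samples\n", sep = "")
  cat("  intercept:", format(x$mu_hat, digits = 4), "\n")
  pt <- x$percent_table
  cat("  % of variance:",
      paste(sprintf("%s %.1f", names(pt), pt), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a multi-kernel fit
#'
#' @param object A [kern_fit].
#' @param ... Unused.
#' @return An object of class `"summary.kern_fit"` with the variance
#'   component table (posterior mean, posterior sd, percent of total) and
#'   MCMC metadata.
#' @export
summary.kern_fit <- function(object, ...) {
  labs <- c(names(object$var_components), "Res")
  post_sd <- apply(object$samples[, labs, drop = FALSE], 2, stats::sd)
  tab <- data.frame(
    term = labs,
    variance = c(object$var_components, object$resid_var),
    post_sd = post_sd,
    percent = object$percent_table[labs],
    row.names = NULL)
  structure(list(model = object$model, trait = object$trait,
                 mu_hat = object$mu_hat, table = tab,
                 meta = object$mcmc_meta,
                 ess = effective_size(object)),
            class = "summary.kern_fit")
}

#' @export
print.summary.kern_fit <- function(x, ...) {
  cat("Model", x$model, "| trait", x$trait, "| intercept",
      format(x$mu_hat, digits = 4), "\n")
  tab <- x$table
  tab$variance <- signif(tab$variance, 4)
  tab$post_sd <- signif(tab$post_sd, 3)
  tab$percent <- round(tab$percent, 1)
  tab$ESS <- round(x$ess[tab$term])
  print(tab, row.names = FALSE)
  cat("retained samples:", x$meta$retained, "(seed", x$meta$seed, ")\n")
  invisible(x)
}

# lag-autocorrelation effective sample size of the variance chains
effective_size <- function(fit) {
  apply(fit$samples[, -1, drop = FALSE], 2, function(v) {
    m <- length(v)
    if (stats::sd(v) < 1e-14) return(m)
    ac <- stats::acf(v, lag.max = min(m - 1, 50), plot = FALSE)$acf[-1]
    pos <- ac[ac > 0.05]
    m / (1 + 2 * sum(pos))
  })
}

#' @export
coef.kern_fit <- function(object, ...) {
  c(mu = object$mu_hat, object$var_components, Res = object$resid_var)
}

#' Predictions from a multi-kernel fit
#'
#' Posterior mean of the linear predictor `mu + sum_k u_k` for every
#' observation, including those whose phenotype was missing or masked
#' during fitting.
#'
#' @param object A [kern_fit].
#' @param which `"all"`, `"masked"` (only hidden observations) or
#'   `"observed"`.
#' @param ... Unused.
#' @return Named numeric vector (names = line ids).
#' @export
predict.kern_fit <- function(object, which = c("all", "masked", "observed"),
                             ...) {
  which <- match.arg(which)
  p <- object$predictions
  switch(which,
         all = p,
         masked = p[object$masked],
         observed = if (length(object$masked)) p[-object$masked] else p)
}

#' @export
fitted.kern_fit <- function(object, ...) object$predictions

#' @export
residuals.kern_fit <- function(object, ...) {
  r <- object$y - object$predictions
  stats::setNames(r, object$obs$gid)
}

#' Diagnostic plots for a multi-kernel fit
#'
#' @param x A [kern_fit].
#' @param type `"trace"` (variance-component chains) or `"fit"` (observed
#'   vs predicted).
#' @param ... Passed to the underlying plotting calls.
#' @export
plot.kern_fit <- function(x, type = c("trace", "fit"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    labs <- colnames(x$samples)[-1]
    old <- graphics::par(mfrow = c(length(labs), 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    for (lab in labs) {
      graphics::plot(x$samples[, lab], type = "l", ylab = lab, xlab = "", ...)
    }
  } else {
    ok <- !is.na(x$y)
    graphics::plot(x$predictions[ok], x$y[ok],
                   xlab = "predicted", ylab = "observed",
                   main = paste(x$model, x$trait), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Simulate phenotypes from a fitted model
#'
#' Draws new phenotype vectors from the fitted data-generating process:
#' `y* = mu_hat + sum_k u_k* + e*` with `u_k* ~ N(0, K_k sigma2_k_hat)`
#' drawn through the cached kernel factorizations and
#' `e* ~ N(0, sigma2_hat I)`. The fit keeps no kernels, so the originating
#' model must be supplied.
#'
#' @param object A [kern_fit].
#' @param nsim Number of replicate phenotype vectors.
#' @param seed Integer seed.
#' @param model The [kern_model] (factorized or not) the fit was produced
#'   from.
#' @param ... Unused.
#' @return Data frame, one column per simulation, rows in observation order.
#' @export
simulate.kern_fit <- function(object, nsim = 1, seed = 1, model, ...) {
  stopifnot(inherits(model, "kern_model"), identical(model$name, object$model))
  model <- factorize_model(model, eigen_tol = object$mcmc_meta$eigen_tol)
  set.seed(as.integer(seed))
  n <- nrow(object$obs)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    y <- rep(object$mu_hat, n)
    for (lab in names(model$factors)) {
      B <- model$factors[[lab]]$B
      y <- y + sqrt(object$var_components[lab]) *
        drop(B %*% stats::rnorm(ncol(B)))
    }
    out[, s] <- y + stats::rnorm(n, 0, sqrt(object$resid_var))
  }
  df <- as.data.frame(out)
  names(df) <- paste0("sim_", seq_len(nsim))
  rownames(df) <- object$obs$gid
  df
}
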