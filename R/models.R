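#' Assemble a multi-environment prediction dataset
#'
#' Binds a line-by-environment phenotype table (one record per line; each
#' line observed in exactly one environment/year) to the pedigree and
#' genomic relationship kernels, in the canonical observation order
#' (environment, then line id) that makes environment-indexed interaction
#' kernels literally block-diagonal.
#'
#' @param pheno Data frame with columns `GID`, `ENV` and one column per
#'   trait; trait values may be `NA`.
#' @param trait Name of the trait column to analyse.
#' @param pedigree Optional pedigree data frame (`id`, `sire`, `dam`); sorted
#'   automatically. Required for models with pedigree terms.
#' @param markers Optional marker matrix (lines x markers, 0/1/2/`NA`).
#'   Required for models with genomic terms.
#' @param qc Apply [qc_markers()] before building G (default `TRUE`).
#' @param max_missing,min_maf QC thresholds passed to [qc_markers()].
#' @return Object of class `"kern_data"`: list with `obs` (data frame `gid`,
#'   `env`, `y` in canonical order), `trait`, entity kernels `A` and/or `G`,
#'   `p` (markers used), and the QC report.
#' @export
kern_data <- function(pheno, trait, pedigree = NULL, markers = NULL,
                      qc = TRUE, max_missing = 0.30, min_maf = 0.05) {
  stopifnot(is.data.frame(pheno), all(c("GID", "ENV") %in% names(pheno)))
  if (!trait %in% names(pheno)) {
    stop("trait '", trait, "' not found in phenotype table")
  }
  gid <- as.character(pheno$GID)
  if (anyDuplicated(gid)) {
    stop("duplicate GID '", gid[which(duplicated(gid))[1]],
         "': lines must be observed exactly once")
  }
  y <- pheno[[trait]]
  if (!is.numeric(y)) stop("trait column '", trait, "' is not numeric")
  obs <- data.frame(gid = gid, env = as.character(pheno$ENV), y = y,
                    stringsAsFactors = FALSE)
  obs <- obs[order(obs$env, obs$gid), , drop = FALSE]
  rownames(obs) <- NULL

  A <- G <- NULL
  p <- NA_integer_
  qc_report <- NULL
  if (!is.null(pedigree)) {
    ped <- topo_sort_pedigree(pedigree, add_founders = TRUE)
    A <- build_A(ped)
    missing_ids <- setdiff(obs$gid, A$ids)
    if (length(missing_ids) > 0) {
      stop("phenotyped line '", missing_ids[1], "' absent from the pedigree")
    }
  }
  if (!is.null(markers)) {
    missing_ids <- setdiff(obs$gid, rownames(markers))
    if (length(missing_ids) > 0) {
      stop("phenotyped line '", missing_ids[1], "' absent from the marker matrix")
    }
    M <- markers[rownames(markers) %in% obs$gid, , drop = FALSE]
    if (qc) {
      M <- qc_markers(M, max_missing = max_missing, min_maf = min_maf)
      qc_report <- attr(M, "qc_report")
    }
    X <- impute_and_standardize(M)
    p <- ncol(X)
    G <- build_G(X)
  }
  structure(list(obs = obs, trait = trait, A = A, G = G, p = p,
                 qc_report = qc_report),
            class = "kern_data")
}

#' @export
print.kern_data <- function(x, ...) {
  cat("<kern_data> trait:", x$trait, "|", nrow(x$obs), "observations in",
      length(unique(x$obs$env)), "environments\n")
  cat("  kernels:", paste(c(if (!is.null(x$A)) "A", if (!is.null(x$G)) "G"),
                          collapse = ", "),
      if (!is.na(x$p)) paste0("(", x$p, " markers)"), "\n")
  invisible(x)
}

.MODEL_TERMS <- list(
  M1 = c("E", "A"),
  M2 = c("E", "A", "AE"),
  M3 = c("E", "G"),
  M4 = c("E", "G", "GE"),
  M5 = c("E", "G", "A"),
  M6 = c("E", "G", "A", "GE", "AE"),
  M7 = c("E", "G", "A", "GA"),
  M8 = c("E", "G", "A", "GA", "GAE"))

#' List the registered models
#'
#' @return Character vector `M1`..`M8`, in order.
#' @export
list_models <- function() names(.MODEL_TERMS)

#' Term labels of a registered model
#'
#' @param name Model name (`"M1"`..`"M8"`).
#' @return Character vector of term labels (subset of E, A, G, AE, GE, GA,
#'   GAE).
#' @export
model_terms <- function(name) {
  if (!name %in% names(.MODEL_TERMS)) {
    stop("unknown model '", name, "'; valid models: ",
         paste(names(.MODEL_TERMS), collapse = ", "))
  }
  .MODEL_TERMS[[name]]
}

#' Bind a registered model to a dataset
#'
#' Builds the observation-level covariance kernel of every term of the
#' requested model: `E` is the environment incidence kernel, `A`/`G` are the
#' entity kernels expanded by the line incidence map, and the interaction
#' terms are Hadamard products (`AE = (Zg A Zg') o (ZE ZE')`, `GE`, `GA =
#' (Zg G Zg') o (Zg A Zg')`, `GAE = GA o (ZE ZE')`).
#'
#' @param data A [kern_data] object.
#' @param name Model name (`"M1"`..`"M8"`).
#' @return Object of class `"kern_model"`: list with `name`, `terms` (named
#'   list of observation kernels), `obs`, `trait`.
#' @export
make_model <- function(data, name) {
  stopifnot(inherits(data, "kern_data"))
  labels <- model_terms(name)
  obs <- data$obs
  envf <- factor(obs$env)
  need_A <- any(c("A", "AE", "GA", "GAE") %in% labels)
  need_G <- any(c("G", "GE", "GA", "GAE") %in% labels)
  if (need_A && is.null(data$A)) {
    stop("model ", name, " needs the pedigree kernel A; supply a pedigree")
  }
  if (need_G && is.null(data$G)) {
    stop("model ", name, " needs the genomic kernel G; supply markers")
  }
  E <- env_kernel(envf, obs_ids = obs$gid)
  Ao <- if (need_A) expand_kernel(data$A, obs$gid, obs_ids = obs$gid) else NULL
  Go <- if (need_G) expand_kernel(data$G, obs$gid, obs_ids = obs$gid) else NULL
  terms <- list()
  for (lab in labels) {
    terms[[lab]] <- switch(lab,
      E = E,
      A = Ao,
      G = Go,
      AE = hadamard(Ao, E, name = "AE"),
      GE = hadamard(Go, E, name = "GE"),
      GA = hadamard(Go, Ao, name = "GA"),
      GAE = hadamard(hadamard(Go, Ao, name = "GA"), E, name = "GAE"))
  }
  structure(list(name = name, terms = terms, obs = obs, trait = data$trait,
                 factors = NULL),
            class = "kern_model")
}

#' @export
print.kern_model <- function(x, ...) {
  cat("<kern_model>", x$name, ":", paste(names(x$terms), collapse = " + "),
      "+ residual |", nrow(x$obs), "observations\n")
  invisible(x)
}

#' Precompute the factorized bases of a model's kernels
#'
#' Eigen-factorizes every term kernel once so that repeated fits on the same
#' dataset (cross-validation folds) reuse the bases.
#'
#' @param model A [kern_model].
#' @param eigen_tol Relative eigenvalue cutoff for [factorize()].
#' @return The model with a `factors` element filled in.
#' @export
factorize_model <- function(model, eigen_tol = 1e-8) {
  stopifnot(inherits(model, "kern_model"))
  if (!is.null(model$factors)) return(model)
  model$factors <- lapply(model$terms, factorize, eigen_tol = eigen_tol)
  model$eigen_tol <- eigen_tol
  model
}
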