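#' Construct a relationship kernel
#'
#' A kernel is a named symmetric positive-semidefinite similarity matrix over
#' entities (lines, environments, or observations), the covariance structure
#' of one random effect.
#'
#' @param K Symmetric numeric matrix.
#' @param ids Entity identifiers (defaults to `rownames(K)`).
#' @param name Short label (e.g. `"A"`, `"G"`).
#' @param provenance Character expression recording how the kernel was built.
#' @param env Optional factor of environment labels (observation kernels
#'   only); marks kernels that are block-diagonal by environment, which
#'   [factorize()] exploits.
#' @return An object of class `"kernel"` (class `c("obs_kernel","kernel")`
#'   when `env` semantics apply) with elements `name`, `ids`, `K`,
#'   `provenance`.
#' @export
kernel <- function(K, ids = rownames(K), name = "K", provenance = name,
                   env = NULL) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (is.null(ids)) stop("kernel needs entity ids (rownames or ids =)")
  ids <- as.character(ids)
  if (length(ids) != nrow(K)) stop("ids length does not match kernel dimension")
  if (anyDuplicated(ids)) stop("duplicate kernel ids")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("kernel matrix '", name, "' is not symmetric")
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  obj <- list(name = name, ids = ids, K = K, provenance = provenance)
  cls <- "kernel"
  if (!is.null(env)) {
    stopifnot(length(env) == nrow(K))
    obj$env <- as.factor(env)
    cls <- c("obs_kernel", "kernel")
  }
  structure(obj, class = cls)
}

#' @export
print.kernel <- function(x, ...) {
  cat("<", paste(class(x)[1]), "> ", x$name, ": ", nrow(x$K), " x ", ncol(x$K),
      "  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
dim.kernel <- function(x) dim(x$K)

min_max_eigen <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  c(min = min(ev), max = max(ev))
}

#' Check a kernel's invariants
#'
#' Verifies symmetry (by construction) and positive semidefiniteness:
#' minimum eigenvalue >= -tol * maximum eigenvalue.
#'
#' @param k A [kernel].
#' @param tol Relative eigenvalue tolerance.
#' @return `TRUE` invisibly, or an error.
#' @export
check_psd <- function(k, tol = 1e-8) {
  mm <- min_max_eigen(k$K)
  if (mm["min"] < -tol * max(mm["max"], 1)) {
    stop("kernel '", k$name, "' is not PSD within tolerance (min eigenvalue ",
         signif(mm["min"], 4), ")")
  }
  invisible(TRUE)
}

#' Expand an entity-level kernel to observation level
#'
#' Given an incidence map assigning each observation to one entity, returns
#' the observation kernel `Z K Z'`, i.e. `result[o1, o2] =
#' K[entity(o1), entity(o2)]`. The expansion is exact integer selection.
#'
#' @param K Entity-level [kernel] (e.g. A over lines, G over lines).
#' @param entity_of Character vector, one entity id per observation.
#' @param obs_ids Observation identifiers (default `names(entity_of)` or
#'   seq along).
#' @param env Optional environment factor to attach (see [kernel]).
#' @return An observation-level kernel.
#' @export
expand_kernel <- function(K, entity_of, obs_ids = NULL, env = NULL) {
  stopifnot(inherits(K, "kernel"))
  entity_of <- as.character(entity_of)
  idx <- match(entity_of, K$ids)
  if (anyNA(idx)) {
    stop("observation entity '", entity_of[which(is.na(idx))[1]],
         "' not present in kernel '", K$name, "'")
  }
  if (is.null(obs_ids)) {
    obs_ids <- names(entity_of)
    if (is.null(obs_ids)) obs_ids <- as.character(seq_along(entity_of))
  }
  M <- K$K[idx, idx, drop = FALSE]
  kernel(M, ids = obs_ids, name = K$name,
         provenance = sprintf("Zg %s Zg'", K$name), env = env %||% factor(rep("all", length(idx))))
}

#' Environment incidence kernel
#'
#' The observation kernel `Z_E Z_E'`: 1 when two observations share an
#' environment, 0 otherwise. This is the covariance structure of the iid
#' random environment main effect.
#'
#' @param env Environment label per observation.
#' @param obs_ids Observation identifiers.
#' @return An observation-level kernel named `"E"`.
#' @export
env_kernel <- function(env, obs_ids = NULL) {
  env <- as.factor(env)
  if (is.null(obs_ids)) {
    obs_ids <- names(env)
    if (is.null(obs_ids)) obs_ids <- as.character(seq_along(env))
  }
  M <- outer(env, env, `==`) * 1
  kernel(M, ids = obs_ids, name = "E", provenance = "ZE ZE'", env = env)
}

#' Hadamard (elementwise) product of observation kernels
#'
#' Builds interaction covariance structures such as
#' `(Zg G Zg') o (ZE ZE')`. PSD is preserved (Schur product theorem). All
#' operands must share the same observation ordering.
#'
#' @param ... Two or more observation kernels.
#' @param name Label for the product (default: concatenated operand names).
#' @return An observation-level kernel; its `provenance` records the operand
#'   expression, and it carries the environment factor if any operand does.
#' @export
hadamard <- function(..., name = NULL) {
  ks <- list(...)
  stopifnot(length(ks) >= 2)
  ids <- ks[[1]]$ids
  env <- NULL
  M <- ks[[1]]$K
  for (k in ks[-1]) {
    if (!identical(k$ids, ids)) {
      stop("hadamard operands have mismatched observation ids/order")
    }
    M <- M * k$K
  }
  for (k in ks) {
    if (!is.null(k$env) && nlevels(as.factor(k$env)) > 1) env <- as.factor(k$env)
  }
  if (is.null(name)) name <- paste(vapply(ks, `[[`, "", "name"), collapse = "")
  prov <- paste0("(", paste(vapply(ks, `[[`, "", "provenance"), collapse = ") o ("), ")")
  kernel(M, ids = ids, name = name, provenance = prov,
         env = env %||% ks[[1]]$env)
}

#' Verify environment block-diagonal structure
#'
#' For a kernel built as a Hadamard product that includes the environment
#' incidence factor, observations sorted by environment give a block-diagonal
#' covariance matrix. Returns `TRUE` iff every entry between observations in
#' different environments is zero.
#'
#' @param K Observation kernel.
#' @param env Environment label per observation (defaults to `K$env`).
#' @param tol Entries with absolute value below `tol` count as zero.
#' @return Logical.
#' @export
verify_block_diagonal <- function(K, env = K$env, tol = 0) {
  stopifnot(inherits(K, "kernel"), !is.null(env))
  env <- as.factor(env)
  same <- outer(env, env, `==`)
  all(abs(K$K[!same]) <= tol)
}

#' Factorize a PSD kernel
#'
#' Eigen-decomposes `K` and returns `B` with `B B' ~= K` (eigenvectors scaled
#' by the square roots of their eigenvalues; eigenvalues below
#' `eigen_tol * max` are dropped). For kernels carrying an environment factor
#' with a block-diagonal structure, the decomposition is done block by block,
#' which is exact and much faster.
#'
#' @param K A [kernel], PSD within tolerance.
#' @param eigen_tol Relative eigenvalue cutoff.
#' @return Object of class `"kernel_factor"`: list with `B` (n x r), `values`
#'   (retained eigenvalues), `ids`.
#' @export
factorize <- function(K, eigen_tol = 1e-8) {
  stopifnot(inherits(K, "kernel"))
  n <- nrow(K$K)
  blockwise <- !is.null(K$env) && nlevels(K$env) > 1 &&
    verify_block_diagonal(K, K$env)
  if (blockwise) {
    Bs <- list(); vals <- numeric(0)
    groups <- split(seq_len(n), K$env)
    cols <- 0L
    # global scale for the cutoff so tiny blocks are treated consistently
    pieces <- lapply(groups, function(ix) {
      eigen(K$K[ix, ix, drop = FALSE], symmetric = TRUE)
    })
    vmax <- max(vapply(pieces, function(e) max(e$values), 0), 1e-300)
    check_neg_eigen(min(vapply(pieces, function(e) min(e$values), 0)), vmax,
                    eigen_tol, K$name)
    keep <- lapply(pieces, function(e) which(e$values > eigen_tol * vmax))
    r <- sum(lengths(keep))
    B <- matrix(0, n, r)
    vals <- numeric(r)
    at <- 0L
    for (gi in seq_along(groups)) {
      kcols <- keep[[gi]]
      if (length(kcols) == 0) next
      ix <- groups[[gi]]
      e <- pieces[[gi]]
      B[ix, at + seq_along(kcols)] <-
        e$vectors[, kcols, drop = FALSE] %*% diag(sqrt(e$values[kcols]),
                                                  length(kcols))
      vals[at + seq_along(kcols)] <- e$values[kcols]
      at <- at + length(kcols)
    }
  } else {
    e <- eigen(K$K, symmetric = TRUE)
    vmax <- max(e$values, 1e-300)
    check_neg_eigen(min(e$values), vmax, eigen_tol, K$name)
    kcols <- which(e$values > eigen_tol * vmax)
    B <- e$vectors[, kcols, drop = FALSE] %*% diag(sqrt(e$values[kcols]),
                                                   length(kcols))
    vals <- e$values[kcols]
  }
  structure(list(B = B, values = vals, ids = K$ids, name = K$name),
            class = "kernel_factor")
}

check_neg_eigen <- function(vmin, vmax, eigen_tol, name) {
  # eigen() roundoff on large dense kernels warrants a slightly looser gate
  # than the construction-time PSD tolerance
  if (vmin < -sqrt(eigen_tol) * max(vmax, 1)) {
    stop("kernel '", name, "' is not PSD beyond tolerance (min eigenvalue ",
         signif(vmin, 4), ")")
  }
  invisible(TRUE)
}

#' Write a kernel as a square CSV
#'
#' First row and first column carry the entity ids.
#'
#' @param k A [kernel].
#' @param path Output path.
#' @export
write_kernel <- function(k, path) {
  df <- as.data.frame(k$K)
  df <- cbind(id = k$ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kernel written by [write_kernel()]
#'
#' @param path CSV path.
#' @param name Kernel label (default: file base name).
#' @return A [kernel].
#' @export
read_kernel <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (!identical(colnames(M), ids)) {
    stop("kernel file row/column ids disagree: ", path)
  }
  kernel(M, ids = ids, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
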