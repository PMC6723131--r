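# Independent brute-force oracles used across the suite.

# Naive recursive-descent additive relationship: a(i,j) defined directly from
# the pedigree recursion, no tabular loop shared with build_A().
oracle_A <- function(ped) {
  ids <- ped$id
  s <- match(ped$sire, ids)
  d <- match(ped$dam, ids)
  a <- function(i, j) {
    if (i == j) {
      f <- if (!is.na(s[i]) && !is.na(d[i])) 0.5 * a(s[i], d[i]) else 0
      return(1 + f)
    }
    if (i < j) { tmp <- i; i <- j; j <- tmp }  # i is the later individual
    val <- 0
    if (!is.na(s[i])) val <- val + a(j, s[i])
    if (!is.na(d[i])) val <- val + a(j, d[i])
    0.5 * val
  }
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) M[i, j] <- M[j, i] <- a(i, j)
  }
  M
}

# Explicit dense incidence matrix for expand()'s Z K Z' cross-check.
incidence_matrix <- function(entity_of, entity_ids) {
  Z <- matrix(0, length(entity_of), length(entity_ids))
  Z[cbind(seq_along(entity_of), match(entity_of, entity_ids))] <- 1
  Z
}

# Small random PSD matrix with unit-scale diagonal.
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(n * n), n)
  K <- tcrossprod(L) / n
  dimnames(K) <- list(paste0("o", 1:n), paste0("o", 1:n))
  K
}

# Shared small simulated dataset (pedigree + markers + phenotypes).
small_sim <- function(seed = 1, n_founders = 30, n_families = 40,
                      mean_family_size = 6, p_markers = 300, n_years = 3,
                      fractions = c(E = 0.3, A = 0.3, G = 0.2, Res = 0.2),
                      ...) {
  simulate_breeding(n_founders = n_founders, n_families = n_families,
                    mean_family_size = mean_family_size,
                    p_markers = p_markers, n_years = n_years,
                    variance_fractions = fractions, seed = seed, ...)
}
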