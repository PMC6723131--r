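#' Simulate a multi-generation breeding pedigree
#'
#' Founders are followed by `n_generations - 1` rounds of crosses among
#' randomly sampled parents of the previous generation; the final round
#' produces full-sib families whose sizes follow a shifted geometric law
#' (minimum 1, capped), mimicking the highly variable family sizes of a
#' breeding pipeline.
#'
#' @param n_founders Number of unrelated founders.
#' @param n_families Number of final crosses (full-sib families).
#' @param n_generations Pedigree depth including the founder generation.
#' @param n_intermediate Individuals per intermediate generation (default
#'   `n_founders`).
#' @param mean_family_size Mean of the geometric family-size law.
#' @param max_family_size Cap on family size.
#' @param seed Integer seed.
#' @return Sorted pedigree data frame (`id`, `sire`, `dam`) with attributes
#'   `lines` (ids of the final-generation lines) and `family` (integer
#'   family index per line).
#' @export
simulate_pedigree <- function(n_founders = 80, n_families = 200,
                              n_generations = 5, n_intermediate = n_founders,
                              mean_family_size = 8, max_family_size = 116,
                              seed = 1) {
  stopifnot(n_founders >= 2, n_families >= 1, n_generations >= 2,
            mean_family_size >= 1, max_family_size >= 1)
  set.seed(as.integer(seed))
  founders <- sprintf("F%04d", seq_len(n_founders))
  ped <- data.frame(id = founders, sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  prev <- founders
  if (n_generations > 2) {
    for (g in seq_len(n_generations - 2)) {
      ids <- sprintf("I%d_%04d", g, seq_len(n_intermediate))
      pairs <- t(vapply(seq_len(n_intermediate),
                        function(i) sample(prev, 2), character(2)))
      ped <- rbind(ped, data.frame(id = ids, sire = pairs[, 1],
                                   dam = pairs[, 2], stringsAsFactors = FALSE))
      prev <- ids
    }
  }
  sizes <- pmin(1L + stats::rgeom(n_families, 1 / mean_family_size),
                as.integer(max_family_size))
  if (length(prev) < 2) stop("infeasible pedigree: need >= 2 parents for crosses")
  fam_pairs <- t(vapply(seq_len(n_families),
                        function(i) sample(prev, 2), character(2)))
  line_ids <- sprintf("L%05d", seq_len(sum(sizes)))
  fam_of <- rep(seq_len(n_families), sizes)
  lines <- data.frame(id = line_ids, sire = fam_pairs[fam_of, 1],
                      dam = fam_pairs[fam_of, 2], stringsAsFactors = FALSE)
  ped <- rbind(ped, lines)
  rownames(ped) <- NULL
  attr(ped, "lines") <- line_ids
  attr(ped, "family") <- stats::setNames(fam_of, line_ids)
  ped
}

#' Simulate marker genotypes by gene dropping
#'
#' Founder haplotypes are drawn under Hardy-Weinberg equilibrium at
#' per-marker minor allele frequencies sampled from a uniform law; each
#' descendant inherits, per locus, one allele chosen uniformly at random
#' from each parent's two alleles (Mendelian sampling; loci unlinked). Full
#' sibs therefore share identical pedigree relationships while their
#' realized marker relationships vary around them.
#'
#' @param ped Sorted pedigree (see [simulate_pedigree()]).
#' @param p_markers Number of biallelic markers.
#' @param maf_range Range of the uniform founder MAF law.
#' @param missing_rate Fraction of calls set to `NA`.
#' @param seed Integer seed.
#' @return Integer matrix (all pedigree individuals x markers) of codes
#'   0/1/2, `NA` for missing, rownames = ids.
#' @export
simulate_genotypes <- function(ped, p_markers = 1000,
                               maf_range = c(0.05, 0.5), missing_rate = 0,
                               seed = 1) {
  stopifnot(is_topo_sorted(ped))
  set.seed(as.integer(seed))
  n <- nrow(ped)
  p <- p_markers
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  H1 <- matrix(0L, n, p)
  H2 <- matrix(0L, n, p)
  draw_founder <- function() as.integer(stats::runif(p) < maf)
  for (i in seq_len(n)) {
    H1[i, ] <- if (is.na(s[i])) draw_founder() else {
      pick <- stats::runif(p) < 0.5
      ifelse(pick, H1[s[i], ], H2[s[i], ])
    }
    H2[i, ] <- if (is.na(d[i])) draw_founder() else {
      pick <- stats::runif(p) < 0.5
      ifelse(pick, H1[d[i], ], H2[d[i], ])
    }
  }
  M <- H1 + H2
  rownames(M) <- ped$id
  colnames(M) <- sprintf("M%05d", seq_len(p))
  if (missing_rate > 0) {
    drop_idx <- which(stats::runif(length(M)) < missing_rate)
    M[drop_idx] <- NA_integer_
  }
  attr(M, "maf") <- maf
  M
}

#' Assign lines to years
#'
#' Each line is phenotyped in exactly one year. Families are placed in the
#' currently smallest year (balanced totals); a configurable fraction of
#' multi-member families is split across two years, mirroring the minority
#' of families observed in more than one cycle.
#'
#' @param ped Pedigree from [simulate_pedigree()] (carries the line/family
#'   attributes).
#' @param n_years Number of years (environments).
#' @param overlap_frac Target fraction of families with members in >= 2
#'   years.
#' @param seed Integer seed.
#' @return Data frame `gid`, `env` (labels `"Y1"`..), one row per line.
#' @export
assign_years <- function(ped, n_years = 4, overlap_frac = 0.15, seed = 1) {
  stopifnot(n_years >= 2, overlap_frac >= 0, overlap_frac <= 1)
  lines <- attr(ped, "lines")
  fam <- attr(ped, "family")
  if (is.null(lines) || is.null(fam)) {
    stop("pedigree lacks line/family attributes; use simulate_pedigree()")
  }
  set.seed(as.integer(seed))
  years <- paste0("Y", seq_len(n_years))
  n_fam <- max(fam)
  fam_sizes <- tabulate(fam, n_fam)
  year_of <- stats::setNames(rep(NA_character_, length(lines)), lines)
  load <- stats::setNames(rep(0, n_years), years)
  # primary year per family: fill the smallest year, random tie-break
  for (f in sample(seq_len(n_fam))) {
    members <- lines[fam == f]
    yr <- names(load)[which.min(load + stats::runif(n_years, 0, 0.5))]
    year_of[members] <- yr
    load[yr] <- load[yr] + length(members)
  }
  n_split_target <- round(overlap_frac * n_fam)
  splittable <- which(fam_sizes >= 2)
  if (n_split_target > length(splittable)) {
    warning("overlap fraction infeasible: only ", length(splittable),
            " families have >= 2 members", call. = FALSE)
    n_split_target <- length(splittable)
  }
  if (n_split_target > 0) {
    chosen <- splittable[sample.int(length(splittable), n_split_target)]
    for (f in chosen) {
      members <- lines[fam == f]
      k <- sample(seq_len(length(members) - 1L), 1)
      moved <- sample(members, k)
      other <- sample(setdiff(years, year_of[members[1]]), 1)
      load[year_of[moved[1]]] <- load[year_of[moved[1]]] - k
      year_of[moved] <- other
      load[other] <- load[other] + k
    }
  }
  data.frame(gid = lines, env = unname(year_of[lines]),
             stringsAsFactors = FALSE)
}

#' Simulate phenotypes from the multi-kernel data-generating process
#'
#' Draws each requested component from its kernel — `E` from the environment
#' incidence kernel, `A`/`G` expanded to observations, interactions as
#' Hadamard products — as `u = B z`, `z ~ N(0, I)`, through [factorize()].
#' Kernels are first normalized to mean diagonal 1 so that the variance
#' fractions are comparable across kernels, and every drawn component is
#' rescaled so its realized variance over observations equals its requested
#' fraction of `total_var` exactly (a scalar rescale, which preserves the
#' kernel covariance shape). The phenotype is the exact sum
#' `mu + sum components + residual`.
#'
#' @param ped Sorted pedigree with line attributes.
#' @param markers Marker matrix over (at least) the lines; needed only when
#'   a genomic fraction is requested.
#' @param years Data frame `gid`, `env` from [assign_years()].
#' @param variance_fractions Named non-negative fractions over
#'   `E, A, G, AE, GE, GA, GAE, Res` (missing names = 0) summing to 1.
#' @param mu Overall mean.
#' @param total_var Target phenotypic variance.
#' @param trait Name of the simulated trait column.
#' @param seed Integer seed.
#' @param eigen_tol Factorization cutoff.
#' @return List: `pheno` (data frame `GID`, `ENV`, trait), `components`
#'   (matrix of the true per-observation effects, including the residual),
#'   `realized_fractions`, `obs` (canonical observation order used).
#' @export
simulate_phenotypes <- function(ped, markers = NULL, years,
                                variance_fractions, mu = 0, total_var = 1,
                                trait = "y", seed = 1, eigen_tol = 1e-8) {
  all_labs <- c("E", "A", "G", "AE", "GE", "GA", "GAE", "Res")
  variance_fractions <- unlist(variance_fractions)  # accept config lists
  vf <- stats::setNames(rep(0, length(all_labs)), all_labs)
  bad <- setdiff(names(variance_fractions), all_labs)
  if (length(bad) > 0) stop("unknown variance fraction label: ", bad[1])
  vf[names(variance_fractions)] <- variance_fractions
  if (any(vf < 0) || abs(sum(vf) - 1) > 1e-8) {
    stop("variance fractions must be non-negative and sum to 1")
  }
  obs <- years[order(years$env, years$gid), , drop = FALSE]
  rownames(obs) <- NULL
  n <- nrow(obs)
  envf <- factor(obs$env)

  need_A <- any(vf[c("A", "AE", "GA", "GAE")] > 0)
  need_G <- any(vf[c("G", "GE", "GA", "GAE")] > 0)
  normalize <- function(k) {
    k$K <- k$K / mean(diag(k$K))
    k
  }
  Ao <- Go <- NULL
  if (need_A) {
    A <- build_A(ped)
    Ao <- normalize(expand_kernel(A, obs$gid, obs_ids = obs$gid))
  }
  if (need_G) {
    if (is.null(markers)) {
      stop("variance fractions request genomic components but no markers given")
    }
    M <- markers[obs$gid, , drop = FALSE]
    # drop markers monomorphic within the phenotyped lines
    M <- qc_markers(M, max_missing = 0.999, min_maf = 1e-9)
    Go <- normalize(build_G(impute_and_standardize(M)))
  }
  E <- env_kernel(envf, obs_ids = obs$gid)
  kern_of <- list(
    E = function() E,
    A = function() Ao,
    G = function() Go,
    AE = function() hadamard(Ao, E, name = "AE"),
    GE = function() hadamard(Go, E, name = "GE"),
    GA = function() hadamard(Go, Ao, name = "GA"),
    GAE = function() hadamard(hadamard(Go, Ao, name = "GA"), E, name = "GAE"))

  set.seed(as.integer(seed))
  comp_labs <- all_labs[vf > 0]
  components <- matrix(0, n, length(comp_labs),
                       dimnames = list(obs$gid, comp_labs))
  rescale <- function(u, target_var) {
    v <- mean((u - mean(u))^2)
    if (v < 1e-300) stop("degenerate component draw (zero variance)")
    u * sqrt(target_var / v)
  }
  for (lab in comp_labs) {
    if (lab == "Res") {
      components[, lab] <- rescale(stats::rnorm(n), vf[lab] * total_var)
    } else {
      fac <- factorize(kern_of[[lab]](), eigen_tol = eigen_tol)
      u <- drop(fac$B %*% stats::rnorm(ncol(fac$B)))
      components[, lab] <- rescale(u, vf[lab] * total_var)
    }
  }
  y <- mu + rowSums(components)
  realized <- apply(components, 2, function(u) mean((u - mean(u))^2)) /
    total_var
  pheno <- data.frame(GID = obs$gid, ENV = obs$env, stringsAsFactors = FALSE)
  pheno[[trait]] <- y
  list(pheno = pheno, components = components, realized_fractions = realized,
       obs = obs, mu = mu, total_var = total_var,
       variance_fractions = vf)
}

#' Simulate a complete breeding-program dataset
#'
#' One call chaining [simulate_pedigree()], [simulate_genotypes()],
#' [assign_years()] and [simulate_phenotypes()], with sub-stream seeds
#' derived from the master seed by fixed offsets. The default variance
#' fractions are a grain-yield-like preset (strong environment and
#' pedigree-by-environment signal); tests use sharper presets.
#'
#' @param n_founders,n_families,n_generations,mean_family_size,max_family_size
#'   Pedigree parameters (see [simulate_pedigree()]).
#' @param p_markers,maf_range,missing_rate Genotype parameters; set
#'   `p_markers = 0` to skip genotypes when no genomic fraction is needed.
#' @param n_years,overlap_frac Year-assignment parameters.
#' @param variance_fractions Named fractions over E, A, G, AE, GE, GA, GAE,
#'   Res summing to 1.
#' @param mu,total_var,trait Phenotype scale.
#' @param seed Master seed.
#' @return List: `pheno`, `pedigree`, `markers` (lines only; `NULL` when
#'   skipped), `truth` (components, realized fractions), `family` (family
#'   index per line).
#' @export
simulate_breeding <- function(n_founders = 80, n_families = 200,
                              n_generations = 5, mean_family_size = 8,
                              max_family_size = 116, p_markers = 1000,
                              maf_range = c(0.05, 0.5), missing_rate = 0,
                              n_years = 4, overlap_frac = 0.15,
                              variance_fractions = c(E = 0.35, A = 0.12,
                                                     G = 0.07, AE = 0.20,
                                                     GE = 0.07, Res = 0.19),
                              mu = 0, total_var = 1, trait = "y", seed = 1) {
  seed <- as.integer(seed)
  ped <- simulate_pedigree(n_founders = n_founders, n_families = n_families,
                           n_generations = n_generations,
                           mean_family_size = mean_family_size,
                           max_family_size = max_family_size, seed = seed + 1L)
  markers <- NULL
  if (p_markers > 0) {
    Mall <- simulate_genotypes(ped, p_markers = p_markers,
                               maf_range = maf_range,
                               missing_rate = missing_rate, seed = seed + 2L)
    markers <- Mall[attr(ped, "lines"), , drop = FALSE]
  }
  years <- assign_years(ped, n_years = n_years, overlap_frac = overlap_frac,
                        seed = seed + 3L)
  sim <- simulate_phenotypes(ped, markers = markers, years = years,
                             variance_fractions = variance_fractions,
                             mu = mu, total_var = total_var, trait = trait,
                             seed = seed + 4L)
  list(pheno = sim$pheno, pedigree = ped, markers = markers,
       truth = list(components = sim$components,
                    realized_fractions = sim$realized_fractions,
                    variance_fractions = sim$variance_fractions,
                    mu = mu, total_var = total_var),
       family = attr(ped, "family"))
}
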