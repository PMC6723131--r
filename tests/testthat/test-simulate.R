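test_that("simulated pedigrees are sorted and family sizes follow the law", {
  ped <- simulate_pedigree(n_founders = 20, n_families = 1000,
                           mean_family_size = 8, max_family_size = 116,
                           seed = 1)
  expect_true(kernpred:::is_topo_sorted(ped))
  fam <- attr(ped, "family")
  sizes <- as.integer(table(fam))
  expect_true(all(sizes >= 1))
  expect_true(max(sizes) <= 116)
  # shifted geometric with mean 8: sample mean and singleton share
  expect_equal(mean(sizes), 8, tolerance = 0.15)
  expect_equal(mean(sizes == 1), 1 / 8, tolerance = 0.35)
  # full sibs share both parents
  m <- names(fam)[fam == fam[[which(sizes[fam] > 1)[1]]]]
  rows <- ped[ped$id %in% m, ]
  expect_length(unique(paste(rows$sire, rows$dam)), 1)
})

test_that("a parent homozygous for the minor allele always transmits it", {
  ped <- simulate_pedigree(n_founders = 10, n_families = 10,
                           mean_family_size = 4, n_generations = 2, seed = 2)
  M <- simulate_genotypes(ped, p_markers = 200, seed = 3)
  lines <- attr(ped, "lines")
  for (gid in lines[1:10]) {
    sire <- ped$sire[ped$id == gid]
    hom <- which(M[sire, ] == 2L)
    expect_true(all(M[gid, hom] >= 1L))
  }
})

test_that("founder allele frequencies follow the configured law", {
  ped <- simulate_pedigree(n_founders = 300, n_families = 1,
                           mean_family_size = 1, n_generations = 2, seed = 4)
  M <- simulate_genotypes(ped, p_markers = 400, maf_range = c(0.05, 0.5),
                          seed = 5)
  founders <- ped$id[is.na(ped$sire)]
  freq <- unname(colMeans(M[founders, ]) / 2)
  maf <- attr(M, "maf")
  expect_equal(freq, maf, tolerance = 0.12)
  expect_equal(mean(pmin(freq, 1 - freq)), 0.275, tolerance = 0.05)
})

test_that("realized full-sib genomic relationship varies around the pedigree value", {
  ped <- simulate_pedigree(n_founders = 120, n_families = 50,
                           mean_family_size = 4, n_generations = 2, seed = 6)
  M <- simulate_genotypes(ped, p_markers = 2000, seed = 7)
  lines <- attr(ped, "lines")
  fam <- attr(ped, "family")
  G <- build_G(impute_and_standardize(qc_markers(M[lines, ])))$K
  A <- build_A(ped)$K[lines, lines]
  g_sib <- a_sib <- numeric(0)
  for (f in unique(fam)) {
    m <- names(fam)[fam == f]
    if (length(m) < 2) next
    pairs <- utils::combn(m, 2)
    g_sib <- c(g_sib, G[t(pairs)])
    a_sib <- c(a_sib, A[t(pairs)])
  }
  # expectation matches the pedigree; segregation adds real spread
  expect_lt(abs(mean(g_sib) - mean(a_sib)), 0.05)
  expect_gt(stats::var(g_sib), 0)
})

test_that("year assignment observes each line once and hits the overlap target", {
  ped <- simulate_pedigree(n_founders = 40, n_families = 150,
                           mean_family_size = 6, seed = 8)
  fam <- attr(ped, "family")
  y0 <- assign_years(ped, n_years = 3, overlap_frac = 0, seed = 9)
  expect_false(any(duplicated(y0$gid)))
  split0 <- vapply(split(y0$env, fam[y0$gid]),
                   function(e) length(unique(e)), 0L)
  expect_true(all(split0 == 1))

  y15 <- assign_years(ped, n_years = 3, overlap_frac = 0.15, seed = 10)
  split15 <- vapply(split(y15$env, fam[y15$gid]),
                    function(e) length(unique(e)), 0L)
  expect_equal(mean(split15 >= 2), 0.15, tolerance = 0.05)
  # years roughly balanced
  expect_lt(diff(range(table(y15$env))) / nrow(y15), 0.2)
})

test_that("phenotype components sum exactly and realize the requested fractions", {
  sim <- simulate_breeding(n_founders = 60, n_families = 80,
                           mean_family_size = 8, p_markers = 400,
                           n_years = 3,
                           variance_fractions = c(E = 0.3, A = 0.2, G = 0.1,
                                                  GE = 0.2, Res = 0.2),
                           seed = 11)
  comp <- sim$truth$components
  y <- sim$pheno$y[match(rownames(comp), sim$pheno$GID)]
  expect_equal(unname(rowSums(comp)), y - sim$truth$mu, tolerance = 1e-12)
  expect_equal(sim$truth$realized_fractions,
               c(E = 0.3, A = 0.2, G = 0.1, GE = 0.2, Res = 0.2),
               tolerance = 1e-10)
  # components are mutually near-orthogonal, so var(y) ~ total
  expect_equal(stats::var(y), 1, tolerance = 0.12)
})

test_that("a pedigree signal is recovered, a pure-noise signal is not", {
  sim1 <- simulate_breeding(n_founders = 60, n_families = 80,
                            mean_family_size = 8, p_markers = 0, n_years = 3,
                            variance_fractions = c(E = 0.2, A = 0.6,
                                                   Res = 0.2), seed = 12)
  d1 <- kern_data(sim1$pheno, "y", pedigree = sim1$pedigree)
  f1 <- fit_gibbs(d1, "M1", n_iter = 3000, burn_in = 1000, seed = 1)
  expect_gt(f1$percent_table["A"], 30)
  expect_gt(f1$var_components["A"], f1$resid_var)

  sim0 <- simulate_breeding(n_founders = 40, n_families = 40,
                            mean_family_size = 8, p_markers = 0, n_years = 2,
                            variance_fractions = c(Res = 1), seed = 13)
  d0 <- kern_data(sim0$pheno, "y", pedigree = sim0$pedigree)
  f0 <- fit_gibbs(d0, "M1", n_iter = 2500, burn_in = 500, seed = 1)
  expect_lt(f0$percent_table["A"], 25)
})

test_that("a planted GxA signal raises M7's fitted GA share", {
  diff_ga <- vapply(1:5, function(s) {
    base <- list(n_founders = 50, n_families = 60, mean_family_size = 7,
                 p_markers = 400, n_years = 2)
    with_ga <- do.call(simulate_breeding, c(base, list(
      variance_fractions = c(E = 0.15, G = 0.15, A = 0.15, GA = 0.35,
                             Res = 0.20), seed = 100 + s)))
    no_ga <- do.call(simulate_breeding, c(base, list(
      variance_fractions = c(E = 0.15, G = 0.15, A = 0.15, Res = 0.55),
      seed = 100 + s)))
    pct <- function(sim) {
      d <- kern_data(sim$pheno, "y", pedigree = sim$pedigree,
                     markers = sim$markers)
      fit_gibbs(d, "M7", n_iter = 1200, burn_in = 400, seed = s)$percent_table["GA"]
    }
    pct(with_ga) - pct(no_ga)
  }, 0)
  expect_gt(mean(diff_ga > 0), 0.5)  # majority of seeds
})
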