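test_that("pearson matches the product-moment formula and guards input", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  obs <- c(1, 2, 3, 4); pred <- c(2, 1, 4, 3)
  hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(hand, 0.6)
  expect_equal(pearson(obs, pred), hand)
  expect_error(pearson(1:3, 1:4), "lengths differ")
  expect_error(pearson(1, 2), "at least 2")
  expect_error(pearson(c(1, 1), c(1, 2)), "zero variance")
})

test_that("weighted mean correlation uses environment-size weights", {
  expect_equal(weighted_mean_corr(c(a = 0.4, b = 0.6), c(a = 100, b = 300)),
               0.55)
  expect_equal(weighted_mean_corr(c(a = 0.2, b = 0.8), c(a = 50, b = 50)),
               0.5)  # equal n -> arithmetic mean
  expect_equal(weighted_mean_corr(c(a = 1, b = 1, c = 1),
                                  c(a = 10, b = 200, c = 3)), 1)
  expect_error(weighted_mean_corr(numeric(0), numeric(0)), "empty")
  expect_error(weighted_mean_corr(c(a = 0.5), c(b = 10)), "keys")
})

test_that("CV1 partitions are near-equal, exhaustive and reproducible", {
  gids <- sprintf("L%02d", 1:10)
  parts <- cv1_partitions(gids, k = 5, n_reps = 3, seed = 2)
  for (p in parts) {
    expect_equal(sort(names(p)), sort(gids))
    expect_true(all(table(p) == 2))
  }
  sizes <- table(cv1_partitions(sprintf("L%02d", 1:11), k = 5, n_reps = 1,
                                seed = 1)[[1]])
  expect_equal(as.integer(sizes), c(3L, 2L, 2L, 2L, 2L))
  expect_identical(cv1_partitions(gids, 5, 2, seed = 9),
                   cv1_partitions(gids, 5, 2, seed = 9))
  expect_false(identical(parts[[1]], parts[[2]]))
  expect_error(cv1_partitions(gids[1:3], k = 5), "exceed")
})

test_that("CV1 approaches the kinship ceiling on high-heritability data", {
  # new lines are predicted through relatives only, so even at heritability
  # ~1 the accuracy is capped by the sib relationship (r ~ sqrt(0.5) for
  # large full-sib families); the fit should get close to the closed-form
  # BLUP run at the true variances
  fr <- c(E = 0.2, A = 0.7, Res = 0.1)
  sim <- small_sim(seed = 51, n_founders = 40, n_families = 25,
                   mean_family_size = 18, p_markers = 0, n_years = 2,
                   fractions = fr)
  d <- kern_data(sim$pheno, "y", pedigree = sim$pedigree)
  cv <- run_cv1(d, "M1", k = 5, n_reps = 1, seed = 3, n_iter = 1500,
                burn_in = 500)
  expect_gt(cv$weighted_mean["mean"], 0.45)
  # ceiling: closed-form BLUP at the generating variances, same folds
  part <- cv1_partitions(d$obs$gid, k = 5, n_reps = 1, seed = 3)[[1]]
  preds <- rep(NA_real_, nrow(d$obs))
  for (f in 1:5) {
    bl <- blup_fixed_variances(d, "M1", variances = fr[c("E", "A")],
                               resid_var = fr["Res"],
                               mask = names(part)[part == f])
    sel <- part[d$obs$gid] == f
    preds[sel] <- bl$predictions[d$obs$gid[sel]]
  }
  r_env <- vapply(split(seq_len(nrow(d$obs)), d$obs$env),
                  function(ix) cor(d$obs$y[ix], preds[ix]), 0)
  ceiling_r <- weighted_mean_corr(r_env, table(d$obs$env)[names(r_env)])
  expect_gt(cv$weighted_mean["mean"], ceiling_r - 0.1)
})

test_that("CV1 on pure noise gives correlations near zero", {
  sim <- small_sim(seed = 52, n_founders = 40, n_families = 40,
                   mean_family_size = 8, p_markers = 0, n_years = 2,
                   fractions = c(Res = 1))
  d <- kern_data(sim$pheno, "y", pedigree = sim$pedigree)
  cv <- run_cv1(d, "M1", k = 5, n_reps = 2, seed = 4, n_iter = 1200,
                burn_in = 400)
  expect_lt(abs(cv$weighted_mean["mean"]), 2 / sqrt(nrow(d$obs) / 2))
})

test_that("every line is held out exactly once per CV1 replicate", {
  sim <- small_sim(seed = 53, n_families = 10, p_markers = 0,
                   fractions = c(E = 0.3, A = 0.4, Res = 0.3))
  d <- kern_data(sim$pheno, "y", pedigree = sim$pedigree)
  parts <- cv1_partitions(d$obs$gid, k = 5, n_reps = 3, seed = 5)
  for (p in parts) {
    held <- unlist(lapply(1:5, function(f) names(p)[p == f]))
    expect_equal(sort(held), sort(d$obs$gid))
  }
})

test_that("V00 predicts a held-out year through relatives only", {
  # two years, each line in exactly one: training never contains a test line
  sim <- small_sim(seed = 54, n_founders = 30, n_families = 25,
                   mean_family_size = 8, p_markers = 0, n_years = 2,
                   fractions = c(E = 0.15, A = 0.70, Res = 0.15))
  d <- kern_data(sim$pheno, "y", pedigree = sim$pedigree)
  v <- run_v00(d, "M1", seed = 6, n_iter = 1500, burn_in = 500)
  expect_equal(v$scheme, "V00")
  expect_equal(v$replicates, 1L)
  expect_true(all(is.na(v$per_env[, "sd"])))
  # strong additive signal transmits across years via kinship
  expect_gt(v$weighted_mean["mean"], 0.3)
  expect_error(run_v00(kern_data(sim$pheno[sim$pheno$ENV == "Y1", ], "y",
                                 pedigree = sim$pedigree), "M1"),
               "at least 2 environments")
})

test_that("environments that cannot be scored are skipped with a warning", {
  r <- c(Y1 = 0.5)
  obs <- data.frame(gid = c("a", "b", "c"), env = c("Y1", "Y1", "Y2"),
                    y = c(1, 2, 3))
  expect_warning(
    out <- kernpred:::score_by_env(obs, c(1.2, 1.9, 2.5), c("Y1", "Y2")),
    "skipped")
  expect_true(is.na(out["Y2"]))
  expect_false(is.na(out["Y1"]))
})
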