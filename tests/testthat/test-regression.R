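# All-subsets BIC regression and the two Monte Carlo null procedures.

test_that("zscore standardizes, is idempotent and rejects degenerate input", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  v <- rnorm(50, 10, 3)
  z <- zscore(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(z), z)
  expect_error(zscore(rep(2, 5)), "zero variance")
  expect_error(zscore(3), "length")
})

test_that("subset enumeration is complete and canonically ordered", {
  s5 <- enumerate_subsets()
  expect_length(s5, 31)
  expect_length(enumerate_subsets("N"), 1)
  expect_length(enumerate_subsets(c("a", "b", "c")), 7)
  sizes <- vapply(s5, length, integer(1))
  expect_true(all(diff(sizes) >= 0)) # ordered by size
  expect_equal(s5[[1]], "N")
  expect_equal(s5[[31]], c("N", "E", "O", "A", "C"))
  expect_equal(sum(duplicated(vapply(s5, paste, "", collapse = "+"))), 0)
})

test_that("OLS fits match a normal-equations oracle", {
  tt <- make_trait_table(40, seed = 2)
  X <- tt[big_five_factors()]

  # exact fit
  f <- fit_ols(X$N, X, "N")
  expect_equal(unname(f$betas), 1, tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)

  set.seed(3)
  for (i in 1:10) {
    y <- rnorm(40)
    subset <- sample(big_five_factors(), sample(1:4, 1))
    f <- fit_ols(y, X, subset)
    o <- ols_normal_equations(y, as.matrix(X), subset)
    expect_equal(unname(f$betas), unname(o$beta), tolerance = 1e-10)
    expect_equal(unname(f$std_errors), unname(o$se), tolerance = 1e-10)
    expect_equal(unname(f$t_stats), unname(o$t), tolerance = 1e-10)
    expect_equal(f$rss, o$rss, tolerance = 1e-10)
  }

  # collinear design is rejected
  X2 <- cbind(as.matrix(X), N2 = X$N)
  expect_error(fit_ols(rnorm(40), X2, c("N", "N2")), "rank deficient")
})

test_that("p-values of noise fits are uniform", {
  tt <- make_trait_table(30, seed = 4)
  set.seed(5)
  p <- replicate(800, {
    fit_ols(rnorm(30), tt[big_five_factors()], "E")$p_values[["E"]]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the BIC convention penalizes size and ignores column order", {
  tt <- make_trait_table(58, seed = 6)
  X <- tt[big_five_factors()]
  set.seed(7)
  y <- zscore(X$N) * 0.8 + rnorm(58, 0, 0.5)

  f1 <- fit_ols(y, X, "N")
  f12 <- fit_ols(y, X, c("N", "E"))
  f21 <- fit_ols(y, X, c("E", "N"))
  # equal-rss counterfactual: one extra parameter costs exactly log(n)
  expect_equal(affectspace:::.bic(f1$rss, 58, 3) - affectspace:::.bic(f1$rss, 58, 2),
               log(58))
  expect_equal(f12$bic, f21$bic, tolerance = 1e-12)
  expect_equal(f12$bic, bic_of(f12))

  # a pure-noise extra predictor usually raises BIC
  set.seed(8)
  worse <- mean(replicate(200, {
    yy <- zscore(X$N) * 0.8 + rnorm(58, 0, 0.5)
    fit_ols(yy, X, c("N", "E"))$bic > fit_ols(yy, X, "N")$bic
  }))
  expect_gt(worse, 0.5)
})

test_that("select_optimal fits all 31 models and returns their minimum", {
  tt <- make_trait_table(60, seed = 9)
  set.seed(10)
  y <- rnorm(60)
  sel <- select_optimal(y, tt)
  expect_length(sel$fits, 31)
  bics <- vapply(sel$fits, `[[`, numeric(1), "bic")
  expect_equal(sel$optimal$bic, min(bics))

  # strong single-factor signal is identified most of the time
  set.seed(11)
  hit <- mean(replicate(40, {
    tt2 <- make_trait_table(200, seed = sample.int(1e6, 1))
    y2 <- 0.5 * zscore(tt2$N) + rnorm(200, 0, 0.6)
    identical(select_optimal(y2, tt2)$optimal$subset, "N")
  }))
  expect_gt(hit, 0.9)
})

test_that("null distributions have the stated size, determinism and ordering", {
  tt <- make_trait_table(40, seed = 12)
  set.seed(13)
  y <- rnorm(40)

  nb <- null_min_bic(y, tt, n_iter = 50, seed = 14)
  expect_length(nb, 50)
  expect_equal(nb, null_min_bic(y, tt, n_iter = 50, seed = 14))

  ns <- null_same_model(y, tt, c("N", "C"), n_iter = 50, seed = 14)
  expect_length(ns, 50)
  expect_equal(ns, null_same_model(y, tt, c("N", "C"), n_iter = 50, seed = 14))

  # same seed -> same permutations -> min over family <= single model
  expect_true(all(nb <= ns + 1e-12))

  # parametric resampling is also reproducible
  np <- null_min_bic(y, tt, n_iter = 20, seed = 15, method = "parametric")
  expect_equal(np, null_min_bic(y, tt, n_iter = 20, seed = 15,
                                method = "parametric"))

  expect_error(null_same_model(y, tt, character(0), 10), "subset")
})

test_that("empirical p-values follow the add-one convention at the boundaries", {
  null <- 1:999
  expect_equal(empirical_p(0, null), 1 / 1000)
  expect_equal(empirical_p(1000, null), 1)
  expect_equal(empirical_p(median(null), null), 0.5, tolerance = 0.01)
  expect_equal(empirical_p(0, null, add_one = FALSE), 0)
  expect_error(empirical_p(1, numeric(0)), "nonempty")
})

test_that("selection reports expose both nulls with p_FWER >= p_same", {
  tt <- make_trait_table(58, seed = 16)
  set.seed(17)
  y <- 0.4 * zscore(tt$N) + rnorm(58, 0, 0.9)
  rep <- trait_model_selection(y, tt, cluster_label = "negative",
                               n_iter = 100, seed = 18)
  expect_s3_class(rep, "selection_report")
  expect_length(rep$null_min_bic, 100)
  expect_length(rep$null_same_model_bic, 100)
  expect_gte(rep$p_fwer_all, rep$p_same)
  expect_equal(rep$optimal$bic,
               min(vapply(rep$fits, `[[`, numeric(1), "bic")))
  expect_output(print(rep), "optimal subset")
})
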