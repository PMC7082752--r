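# Adaptive trial selection, evidence accounting, and the inverse-MDS
# dissimilarity estimator.

test_that("lift-the-weakest selection honors deficit, weakest pair and tie-breaking", {
  ids <- sprintf("i%02d", 1:54)
  ev <- empty_evidence(ids)

  # all ties: lowest indices win
  expect_equal(select_next_trial(ev, 10), 1:10)

  # a single weak pair must be included
  ev2 <- matrix(10, 12, 12)
  diag(ev2) <- 0
  ev2[3, 9] <- ev2[9, 3] <- 0
  picked <- select_next_trial(ev2, 4)
  expect_true(all(c(3, 9) %in% picked))
  # all other pairs are saturated, so the trial stays at the minimum size
  expect_length(picked, 3)

  # after a full session the argmin pair is still included
  coh <- tiny_cohort(1, seed = 21)
  s <- simulate_session(coh$spaces[[1]], arrangement_protocol(), seed = 22)
  idx <- which(upper.tri(s$evidence), arr.ind = TRUE)
  weakest <- idx[which.min(s$evidence[upper.tri(s$evidence)]), ]
  again <- select_next_trial(s$evidence, 10)
  expect_true(all(weakest %in% again))

  expect_error(select_next_trial(matrix(0, 1, 1), 10), "at least 2")
})

test_that("evidence updates touch exactly the within-trial pairs, by squared distance", {
  ids <- letters[1:10]
  ev <- empty_evidence(ids)

  # 2-item trial: exactly one pair
  t2 <- list(items = c(2, 5), coords = rbind(c(0, 0), c(0.6, 0)))
  ev2 <- update_evidence(ev, t2)
  expect_equal(sum(ev2[upper.tri(ev2)] > 0), 1)
  expect_equal(ev2[2, 5], 0.36)

  # identical placement carries zero evidence
  t0 <- list(items = c(1, 3), coords = rbind(c(0.2, 0.2), c(0.2, 0.2)))
  expect_equal(update_evidence(ev, t0), ev)

  # 10-item trial: exactly choose(10, 2) = 45 pairs updated
  set.seed(1)
  t10 <- list(items = 1:10, coords = matrix(runif(20, -0.7, 0.7), ncol = 2))
  ev10 <- update_evidence(ev, t10)
  expect_equal(sum(ev10[upper.tri(ev10)] > 0), 45)

  expect_error(update_evidence(ev, list(item_ids = "zz",
                                        coords = rbind(c(0, 0)))),
               "unknown item")
})

test_that("DSV vectorization is row-major upper triangle and round-trips", {
  m <- random_dsm(5, seed = 3)
  dimnames(m) <- list(letters[1:5], letters[1:5])
  v <- dsm_to_dsv(m)
  expect_length(v, 10)
  expect_equal(unname(v[1:4]), unname(m[1, 2:5])) # first row block
  expect_equal(unname(v[5]), unname(m[2, 3]))     # then second row
  expect_equal(names(v)[1], "a|b")
  expect_equal(dsv_to_dsm(v, letters[1:5]), m)

  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(unname(dsm_to_dsv(two)), 0.5)

  big <- random_dsm(54, seed = 4)
  expect_length(dsm_to_dsv(big), 1431)

  asym <- m
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(dsm_to_dsv(asym), "symmetric")
})

test_that("scale_dsv divides by the maximum and is scale invariant", {
  expect_equal(scale_dsv(c(2, 4, 8)), c(0.25, 0.5, 1))
  set.seed(5)
  v <- runif(100, 0.01, 3)
  expect_equal(max(scale_dsv(v)), 1)
  expect_equal(scale_dsv(7 * v), scale_dsv(v))
  expect_error(scale_dsv(rep(0, 5)), "degenerate")
  expect_error(scale_dsv(c(-1, 2)), "nonnegative")
})

test_that("a single all-item trial reproduces its own screen distances", {
  set.seed(6)
  coords <- matrix(rnorm(16), ncol = 2)
  d <- as.matrix(dist(coords))
  session <- list(item_ids = sprintf("s%d", 1:8),
                  trials = list(list(trial_index = 1, items = 1:8,
                                     coords = coords)))
  est <- estimate_dsm(session)
  expect_true(est$converged)
  # proportional to the screen distances, unit-RMS normalized
  expect_equal(unname(est$dsm / est$dsm[1, 2]), unname(d / d[1, 2]),
               tolerance = 1e-8)
  expect_equal(sqrt(mean(dsm_to_dsv(est$dsm)^2)), 1, tolerance = 1e-8)
})

test_that("inverse MDS recovers planted spaces and is trial-order invariant", {
  # small planted space for speed; noiseless placements
  stim <- make_stimulus_set(3, 4, seed = 31)
  tt <- make_trait_table(1, seed = 32)
  sp <- make_planted_spaces(stim, tt, effect_spec(slopes = NULL),
                            seed = 33)[[1]]
  prot <- arrangement_protocol(max_items = 6, placement_noise_sd = 0)
  s <- simulate_session(sp, prot, seed = 34)
  est <- estimate_dsm(s)
  r <- cor(dsm_to_dsv(est$dsm), dsm_to_dsv(sp$true_dsm))
  expect_gt(r, 0.99)

  # permuting trial order leaves the estimate unchanged (up to tol)
  s_perm <- s
  set.seed(35)
  s_perm$trials <- s$trials[sample(length(s$trials))]
  est_perm <- estimate_dsm(s_perm)
  expect_equal(est_perm$dsm, est$dsm, tolerance = 1e-4)

  # incomplete session: name the uncovered pair
  s_cut <- s
  s_cut$trials <- s$trials[1]
  expect_error(estimate_dsm(s_cut), "does not cover pair")
})

test_that("estimator is invariant to rescaling any single trial's coordinates", {
  stim <- make_stimulus_set(2, 4, seed = 41)
  tt <- make_trait_table(1, seed = 42)
  sp <- make_planted_spaces(stim, tt, effect_spec(slopes = NULL),
                            seed = 43)[[1]]
  s <- simulate_session(sp, arrangement_protocol(max_items = 5,
                                                 placement_noise_sd = 0.03),
                        seed = 44)
  est <- estimate_dsm(s)
  s2 <- s
  s2$trials[[2]]$coords <- s2$trials[[2]]$coords * 3.7
  est2 <- estimate_dsm(s2)
  expect_equal(est2$dsm, est$dsm, tolerance = 1e-4)
})
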