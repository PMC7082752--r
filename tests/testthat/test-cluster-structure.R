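# Group-median space, complete linkage, silhouette validation and the
# cluster-dispersion statistic.

test_that("group_median is the elementwise median and matches a sort oracle", {
  expect_equal(group_median(rbind(c(0.2, 0.4, 0.9)))$median_dsv,
               c(0.2, 0.4, 0.9))
  expect_equal(group_median(rbind(c(0, 0, 0), c(1, 1, 1)))$median_dsv,
               c(0.5, 0.5, 0.5))

  set.seed(1)
  m <- matrix(runif(5 * 20), nrow = 5)
  gm <- group_median(m)$median_dsv
  oracle <- apply(m, 2, function(col) {
    s <- sort(col)
    (s[3]) # n = 5: middle element
  })
  expect_equal(gm, oracle)
  expect_equal(gm, apply(m, 2, median))

  expect_error(group_median(list(c(1, 2), c(1, 2, 3))), "equal length")
})

test_that("complete linkage reproduces the hand-computed 3-item dendrogram", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 5
  d[2, 3] <- d[3, 2] <- 4
  dend <- complete_linkage(d)
  expect_equal(dend$height, c(1, 5)) # merge {1,2} at 1, then all at max
  expect_equal(unname(cut_dendrogram(dend, 2)), c(1, 1, 2)) # {1,2} vs {3}
})

test_that("complete linkage matches a naive O(n^3) agglomeration on random instances", {
  for (i in 1:50) {
    n <- sample(3:7, 1)
    dsm <- random_dsm(n, seed = 100 + i)
    dend <- complete_linkage(dsm)
    expect_equal(dend$height, naive_complete_linkage_heights(dsm),
                 tolerance = 1e-12)
    expect_true(all(diff(dend$height) >= 0)) # monotone merges
    expect_length(dend$height, n - 1)
  }
})

test_that("dendrogram cuts are exhaustive, nested and respect k bounds", {
  dsm <- random_dsm(12, seed = 7)
  dend <- complete_linkage(dsm)
  expect_equal(unname(cut_dendrogram(dend, 1)), rep(1, 12))
  expect_equal(length(unique(cut_dendrogram(dend, 12))), 12)
  for (k in 2:11) {
    a_prev <- cut_dendrogram(dend, k - 1)
    a <- cut_dendrogram(dend, k)
    expect_equal(length(unique(a)), k)
    # refinement: items sharing a cluster at k share one at k - 1
    tab <- table(a, a_prev)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  expect_error(cut_dendrogram(dend, 0), "between")
  expect_error(cut_dendrogram(dend, 13), "between")
})

test_that("silhouette matches direct evaluation and the cluster package on small instances", {
  skip_if_not_installed("cluster")
  for (i in 1:20) {
    n <- sample(4:8, 1)
    dsm <- random_dsm(n, seed = 200 + i)
    k <- sample(2:(n - 1), 1)
    assignment <- cut_dendrogram(complete_linkage(dsm), k)
    ours <- silhouette_index(dsm, assignment)
    expect_equal(ours, silhouette_direct(dsm, assignment),
                 tolerance = 1e-12)
    sil <- cluster::silhouette(as.integer(assignment), dmatrix = dsm)
    expect_equal(ours, mean(sil[, "sil_width"]), tolerance = 1e-12)
    expect_true(ours >= -1 && ours <= 1)
  }
  expect_error(silhouette_index(random_dsm(4, 1), rep(1, 4)), "k < 2")
})

test_that("silhouette is high for separated blobs and near zero for random dissimilarities", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
               matrix(rnorm(20, 5, 0.1), ncol = 2))
  dsm <- as.matrix(dist(pts))
  expect_gt(silhouette_index(dsm, rep(1:2, each = 10)), 0.8)

  rnd <- random_dsm(20, seed = 10)
  a <- cut_dendrogram(complete_linkage(rnd), 3)
  expect_lt(abs(silhouette_index(rnd, a)), 0.4)
})

test_that("scan_k selects planted structure and handles monotone profiles", {
  # planted 2-cluster data: global max at k = 2
  set.seed(11)
  pts <- rbind(matrix(rnorm(30, 0, 0.15), ncol = 2),
               matrix(rnorm(30, 4, 0.15), ncol = 2))
  prof <- scan_k(as.matrix(dist(pts)), 2:8)
  expect_equal(prof$k[which.max(prof$silhouette)], 2)
  expect_true(2 %in% prof$selected_k)

  # on a monotone-decreasing profile only the global max (k = 2) remains
  if (all(diff(prof$silhouette) < 0)) {
    expect_equal(prof$selected_k, 2L)
  }
  expect_equal(prof$selected_k[1], 2)

  # planted 4-in-2 hierarchy: local maxima at both 2 and 4
  coh <- tiny_cohort(8, seed = 12)
  dsvs <- t(vapply(coh$spaces, function(s) scale_dsv(dsm_to_dsv(s$true_dsm)),
                   numeric(1431)))
  prof2 <- scan_k(group_median(dsvs), 2:8)
  expect_true(all(c(2, 4) %in% prof2$selected_k))

  expect_error(scan_k(random_dsm(5, 1), 20:25), "k_range")
})

test_that("dispersion implements median within-cluster distance over cardinality", {
  # 2-item cluster, pair dissimilarity 0.6 -> 0.3
  assignment <- c(1, 1, 2, 2)
  dsv <- rep(0, 6)
  dsv[1] <- 0.6 # pair (1,2)
  expect_equal(dispersion(dsv, assignment, 1), 0.3)

  # 3-item cluster with distances {0.2, 0.4, 0.9} -> median 0.4 / 3
  a2 <- c(1, 1, 1, 2, 2)
  d2 <- numeric(10)
  d2[c(1, 2, 5)] <- c(0.2, 0.4, 0.9) # pairs (1,2), (1,3), (2,3)
  expect_equal(dispersion(d2, a2, 1), 0.4 / 3)

  # equal distances d -> d / |c| for any size
  for (size in 2:5) {
    n <- size + 2
    a <- c(rep(1, size), rep(2, 2))
    d <- rep(0.5, choose(n, 2))
    expect_equal(dispersion(d, a, 1), 0.5 / size)
  }

  expect_error(dispersion(rep(0.1, 6), c(1, 2, 2, 2), 1), "singleton")
})

test_that("dispersion tables are participant-invariant in the expected ways", {
  coh <- tiny_cohort(4, seed = 13)
  sol <- coh$spaces[[1]]$partition
  raw <- t(vapply(coh$spaces, function(s) dsm_to_dsv(s$true_dsm),
                  numeric(1431)))
  scaled <- t(apply(raw, 1, scale_dsv))

  # identical participants give identical rows
  dup <- rbind(scaled[1, ], scaled[1, ])
  tab <- dispersion_table(dup, sol)
  expect_equal(unlist(tab[1, -1]), unlist(tab[2, -1]))

  # doubling raw distances changes nothing after scaling
  tab1 <- dispersion_table(t(apply(raw, 1, scale_dsv)), sol)
  tab2 <- dispersion_table(t(apply(2 * raw, 1, scale_dsv)), sol)
  expect_equal(tab1[-1], tab2[-1])

  # permuting participants permutes rows
  perm <- c(3, 1, 4, 2)
  tab_perm <- dispersion_table(scaled[perm, ], sol)
  expect_equal(unname(as.matrix(tab_perm[-1])),
               unname(as.matrix(dispersion_table(scaled, sol)[-1]))[perm, ])
})
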