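test_that("null data produce no spurious significant clusters and errors are raised", {
  set.seed(10)
  a <- matrix(rnorm(12 * 60), 12)
  hits <- 0
  for (s in 1:5) {
    res <- cluster_permutation_test(a, a[sample(12), ],
                                    perm_config(n_permutations = 200,
                                                seed = s))
    hits <- hits + res$significant
  }
  expect_lte(hits, 1)

  expect_error(cluster_permutation_test(a[1, , drop = FALSE], a),
               "two trials")
  expect_error(cluster_permutation_test(a, a[, 1:10]), "time axis")
})

test_that("a strong offset yields a significant cluster overlapping its window", {
  set.seed(3)
  T_len <- 300
  a <- matrix(rnorm(20 * T_len), 20)
  b <- matrix(rnorm(20 * T_len), 20)
  b[, 101:200] <- b[, 101:200] + 5
  res <- cluster_permutation_test(a, b, perm_config(seed = 1))
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start <= 200 & sig$end >= 101))
})

test_that("Monte-Carlo p agrees with the exhaustive relabeling oracle", {
  set.seed(21)
  a <- matrix(rnorm(4 * 6), 4)
  b <- matrix(rnorm(4 * 6, mean = 1.2), 4)
  ex <- exact_cluster_p(a, b)
  res <- cluster_permutation_test(a, b,
                                  perm_config(n_permutations = 2000,
                                              seed = 5))
  expect_gt(nrow(res$clusters), 0)
  mc_p <- min(res$clusters$p)
  se <- sqrt(ex$p * (1 - ex$p) / 2000)
  expect_lt(abs(mc_p - ex$p), 4 * se + 2 / 2000)
})

test_that("permutation p-values are reproducible and invariant to trial order", {
  set.seed(9)
  a <- matrix(rnorm(15 * 80), 15)
  b <- matrix(rnorm(15 * 80, mean = 0.5), 15)
  r1 <- cluster_permutation_test(a, b, perm_config(seed = 7))
  r2 <- cluster_permutation_test(a, b, perm_config(seed = 7))
  expect_identical(r1$clusters, r2$clusters)
  # trial order: cluster geometry and masses are exactly invariant; the
  # Monte-Carlo p can move within binomial error of the sampled null
  r3 <- cluster_permutation_test(a[sample(15), ], b[sample(15), ],
                                 perm_config(seed = 7))
  expect_equal(r1$clusters[c("start", "end", "mass")],
               r3$clusters[c("start", "end", "mass")], tolerance = 1e-10)
  expect_lt(max(abs(r1$clusters$p - r3$clusters$p)), 0.05)
})

test_that("scaling the effect up never shrinks the significant time extent", {
  set.seed(12)
  a <- matrix(rnorm(15 * 120), 15)
  b0 <- matrix(rnorm(15 * 120), 15)
  extent <- sapply(c(0, 1, 2, 4), function(es) {
    b <- b0
    b[, 40:80] <- b[, 40:80] + es
    res <- cluster_permutation_test(a, b, perm_config(seed = 2))
    sig <- res$clusters[res$clusters$significant, ]
    if (!nrow(sig)) 0 else sum(sig$end - sig$start + 1)
  })
  expect_true(all(diff(extent) >= 0))
  expect_gt(extent[4], 0)
})

test_that("structure pooling concatenates trials across contacts", {
  g1 <- make_contact_gpt(n_per = 15, effect = 2, seed = 31,
                         contact = contact_row())
  cfg <- perm_config(seed = 4)
  pooled1 <- structure_pooled_test(list(g1), cfg)
  direct <- cluster_permutation_test(
    g1$values[g1$conditions == "angry", ],
    g1$values[g1$conditions == "happy", ], cfg, g1$time_s)
  expect_equal(pooled1$clusters, direct$clusters)

  # duplicating a contact doubles trial counts but keeps cluster geometry
  pooled2 <- structure_pooled_test(list(g1, g1), cfg)
  expect_equal(pooled2$n_a, 2 * pooled1$n_a)
  expect_equal(pooled2$n_b, 2 * pooled1$n_b)
  if (nrow(pooled1$clusters) && nrow(pooled2$clusters)) {
    big1 <- pooled1$clusters[which.max(abs(pooled1$clusters$mass)), ]
    big2 <- pooled2$clusters[which.max(abs(pooled2$clusters$mass)), ]
    expect_lt(abs(big1$start - big2$start), 15)
  }

  g2 <- make_contact_gpt(n_per = 15, seed = 32,
                         contact = contact_row(label = "AMYGDALA"))
  expect_error(structure_pooled_test(list(g1, g2), cfg), "pooled")
})
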