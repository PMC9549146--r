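test_that("MCC and NMCC follow the confusion-count formula and conventions", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(10, 0, 10, 0), 0)  # single-class predictions
  expect_equal(mcc(30, 20, 10, 5), 550 / sqrt(40 * 35 * 30 * 25))
  expect_equal(mcc(0, 10, 0, 10), 0)
  expect_error(mcc(0, 0, 0, 0), "all zero")

  expect_equal(nmcc(10, 10, 0, 0), 1)
  expect_equal(nmcc(10, 0, 10, 0), 0.5)  # chance level
  expect_equal(nmcc(0, 0, 10, 10), 0)
})

test_that("condition-mean augmentation triples the set and subtracts training means only", {
  set.seed(5)
  x <- matrix(rnorm(4 * 5), 4)
  labels <- c("angry", "angry", "happy", "happy")
  aug <- augment_trials(x, labels)
  expect_equal(nrow(aug$x), 12)
  expect_equal(aug$labels, rep(labels, 3))
  expect_equal(aug$source, rep(1:4, 3))

  # hand-computed expectation
  m_a <- colMeans(x[1:2, ])
  m_h <- colMeans(x[3:4, ])
  expect_identical(aug$x, rbind(x, sweep(x, 2, m_a, "-"),
                                sweep(x, 2, m_h, "-")))

  # a trial equal to the angry mean becomes all-zeros in the angry-mean block
  x2 <- x
  x2[1, ] <- m_a2 <- colMeans(rbind(x[1, ], x[1, ]))
  aug2 <- augment_trials(rbind(x[1, ], x[1, ], x[3:4, ]), labels)
  expect_equal(unname(aug2$x[5, ]), rep(0, 5))

  expect_error(augment_trials(x, rep("angry", 4)), "both conditions")
})

test_that("interval features follow the configured order and degenerate conventions", {
  tt <- gpt_axis
  const <- matrix(2.5, 1, length(tt))
  f <- extract_features(const, tt)
  expect_equal(ncol(f), 15)
  expect_equal(unname(f[1, 1:5]), c(2.5, 0, 2.5, 0, 0))

  # toy ramp: closed-form moments of a linear sample
  ramp <- matrix(seq_along(tt), 1)
  fr <- extract_features(ramp, tt)
  iv1 <- which(tt >= 0.2 & tt < 0.4)
  v <- seq_along(tt)[iv1]
  d <- v - mean(v)
  expect_equal(unname(fr[1, 1]), mean(v))
  expect_equal(unname(fr[1, 2]), sd(v))
  expect_equal(unname(fr[1, 3]), median(v))
  expect_equal(unname(fr[1, 4]), mean(d^3) / mean(d^2)^1.5)
  expect_equal(unname(fr[1, 5]), mean(d^4) / mean(d^2)^2 - 3)

  expect_error(extract_features(const, tt,
                                feature_config(list(c(2, 3)))),
               "samples")
})

test_that("per-contact decoding finds a planted contrast and stays at chance on constants", {
  g_eff <- make_contact_gpt(n_per = 30, effect = 3, seed = 41,
                            contact = contact_row())
  res <- evaluate_contact(g_eff, fast_space(), seed = 2)
  expect_true(res$significant)
  expect_gt(res$mean_nmcc, 0.8)
  expect_equal(length(res$fold_nmcc), 10)
  expect_true(all(res$fold_nmcc >= 0 & res$fold_nmcc <= 1))

  # constant features in both classes: chance by the zero-factor convention
  tt <- gpt_axis
  g_const <- gpt(matrix(1, 40, length(tt)), tt,
                 rep(c("angry", "happy"), each = 20))
  res_c <- evaluate_contact(g_const, fast_space(), seed = 2)
  expect_equal(res_c$fold_nmcc, rep(0.5, 10))
  expect_false(res_c$significant)

  expect_error(evaluate_contact(
    gpt(matrix(rnorm(8 * length(tt)), 8), tt,
        rep(c("angry", "happy"), each = 4)), fast_space()),
    "stratified CV")
})

test_that("decoding is reproducible under a fixed seed and searches the grid", {
  g <- make_contact_gpt(n_per = 25, effect = 1.5, seed = 43,
                        contact = contact_row())
  r1 <- evaluate_contact(g, fast_space(), seed = 9)
  r2 <- evaluate_contact(g, fast_space(), seed = 9)
  expect_identical(r1$fold_nmcc, r2$fold_nmcc)

  tiny_grid <- search_space(n_estimators = 50, max_depth = c(2, 6),
                            p_features = 0.5)
  r3 <- evaluate_contact(g, tiny_grid, seed = 9)
  expect_true(r3$best_params$max_depth %in% c(2, 6))
})

test_that("null contacts are not systematically decodable", {
  # small batch here; the full 200-contact calibration lives in the
  # acceptance suite
  means <- sapply(1:10, function(s) {
    g <- make_contact_gpt(n_per = 20, effect = 0, seed = 100 + s,
                          contact = contact_row())
    evaluate_contact(g, fast_space(50), seed = s)$mean_nmcc
  })
  expect_lt(abs(mean(means) - 0.5), 0.1)
})
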