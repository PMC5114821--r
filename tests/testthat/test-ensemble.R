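test_that("separable data is learned with near-zero round errors", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 8), 30), matrix(rnorm(200, 0), 100))
  y <- rep(c(1L, 0L), c(30, 100))
  fit <- imbboost(x, y, rounds = 3, seed = 31)
  expect_true(all(fit$epsilons <= 1e-3))
  expect_identical(predict(fit, x, type = "class"), y)
})

test_that("single-class data and dimension mismatches are rejected", {
  x <- matrix(rnorm(20), 10)
  expect_error(imbboost(x, rep(1L, 10)), "both classes")
  d <- gauss_blobs(10, 40, seed = 32)
  fit <- imbboost(d$x, d$y, rounds = 2, seed = 32)
  expect_error(predict(fit, matrix(0, 1, 5)), "dimension")
})

test_that("the ensemble probability is a convex combination of base probabilities", {
  d <- gauss_blobs(15, 80, shift = 1.2, seed = 33)
  fit <- imbboost(d$x, d$y, rounds = 5, seed = 33)
  xt <- matrix(rnorm(40), 20)
  p <- predict(fit, xt)
  expect_true(all(p >= 0 & p <= 1))
  base_p <- sapply(fit$base_models, ligbind:::klr_prob, x = xt)
  expect_true(all(p >= apply(base_p, 1, min) - 1e-12))
  expect_true(all(p <= apply(base_p, 1, max) + 1e-12))
  # a single-member ensemble returns that member's probability
  one <- fit
  one$base_models <- fit$base_models[1]
  one$alphas <- fit$alphas[1]
  expect_equal(predict(one, xt), base_p[, 1], tolerance = 1e-12)
})

test_that("training is bit-reproducible for a fixed seed and weights stay normalized", {
  d <- gauss_blobs(20, 300, shift = 1.5, seed = 34)
  f1 <- imbboost(d$x, d$y, rounds = 4, seed = 99)
  f2 <- imbboost(d$x, d$y, rounds = 4, seed = 99)
  expect_identical(f1$alphas, f2$alphas)
  expect_identical(f1$epsilons, f2$epsilons)
  xt <- matrix(rnorm(30), 15)
  expect_identical(predict(f1, xt), predict(f2, xt))
  expect_equal(sum(f1$neg_weights), 1, tolerance = 1e-9)
  # retained rounds always have eps < 0.5 and positive vote weights
  expect_true(all(f1$epsilons < 0.5))
  expect_true(all(f1$alphas > 0))
})

test_that("beta = 1 with full-pool rounds reproduces the classical AdaBoost trace", {
  d <- gauss_blobs(40, 160, shift = 1.6, seed = 35)
  ratio_full <- sum(d$y == 0) / sum(d$y == 1)
  fit <- imbboost(d$x, d$y, rounds = 4, ratio = ratio_full, beta = 1,
                  gamma = 0.3, cost = 1, max_centers = 200L, seed = 35)
  ref <- oracle_adaboost_trace(d$x, d$y, rounds = 4, gamma = 0.3, cost = 1)
  expect_equal(fit$epsilons, ref$epsilons, tolerance = 1e-8)
  expect_equal(fit$alphas, ref$alphas, tolerance = 1e-8)
  expect_equal(fit$neg_weights, ref$neg_weights, tolerance = 1e-8)
})

test_that("uninformative features make every round a coin flip and training stops", {
  # constant features: the base classifier can only return probability 1/2,
  # so eps = 0.5 in every round and no round is ever retained
  members <- integer(10)
  for (s in 1:10) {
    x <- matrix(1, 120, 3)
    y <- rep(c(1L, 0L), c(30, 90))
    fit <- tryCatch(imbboost(x, y, rounds = 5, seed = s),
                    ligbind_training_error = function(e) NULL)
    members[s] <- if (is.null(fit)) 0L else length(fit$alphas)
  }
  expect_gte(sum(members <= 1L), 9L)
})

test_that("models survive serialization bit for bit and bad archives fail loudly", {
  d <- gauss_blobs(12, 60, seed = 36)
  fit <- imbboost(d$x, d$y, rounds = 3, seed = 36)
  path <- withr::local_tempfile(fileext = ".json")
  save_imbboost(fit, path)
  back <- load_imbboost(path)
  set.seed(360)
  xt <- matrix(rnorm(200), 100)
  expect_identical(predict(fit, xt), predict(back, xt))
  # truncated archive
  full <- readLines(path, warn = FALSE)
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(full, collapse = ""), 1, 200), trunc_path)
  expect_error(load_imbboost(trunc_path), class = "ligbind_format_error")
  # version mismatch
  payload <- jsonlite::read_json(path)
  payload$version <- "999"
  v_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, v_path, auto_unbox = TRUE, digits = I(17))
  expect_error(load_imbboost(v_path), "version",
               class = "ligbind_format_error")
})

test_that("config validation catches out-of-range parameters", {
  expect_error(imbboost_config(beta = 0), "beta")
  expect_error(imbboost_config(beta = 1.2), "beta")
  expect_error(imbboost_config(rounds = 0), "rounds")
  expect_error(imbboost_config(ratio = -1), "ratio")
  d <- gauss_blobs(10, 30, seed = 37)
  expect_error(imbboost(d$x, d$y, bogus = 1), "unknown config")
})
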