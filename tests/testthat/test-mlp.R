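# MLP classifier.

test_that("hidden width agrees with an independent nearest-integer oracle", {
  oracle <- function(n) {
    q <- n %/% 10L
    r <- n %% 10L
    as.integer(q + (r >= 5L))  # ties away from zero for positive n
  }
  for (n in 201:806) expect_identical(hidden_width(n), oracle(n))
  expect_identical(suppressWarnings(hidden_width(198)), 20L)
  expect_warning(hidden_width(100), "201-806")
  expect_error(hidden_width(0), ">= 1")
})

test_that("built models have rule-consistent shapes and seeded init", {
  cfg <- mlp_config(402, seed = 4)
  m <- mlp_build(cfg)
  expect_identical(dim(m$params$W1), c(402L, 40L))
  expect_identical(dim(m$params$W2), c(40L, 2L))
  expect_identical(m$params$b1, numeric(40))
  expect_identical(mlp_build(cfg)$params, m$params)
  expect_false(identical(mlp_build(mlp_config(402, seed = 5))$params,
                         m$params))
  # degenerate width: the sizing rule gives zero hidden units
  expect_error(mlp_config(1), "too small")
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(31)
  n <- 8; p <- 5; h <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- cbind(rep(c(1, 0), length.out = n), rep(c(0, 1), length.out = n))
  params <- list(W1 = matrix(rnorm(p * h, sd = 0.3), p, h), b1 = rnorm(h),
                 W2 = matrix(rnorm(h * 2, sd = 0.3), h, 2), b2 = rnorm(2))
  l2 <- 1e-4
  lg <- wristrf:::mlp_loss_grad(params, x, y, l2)
  eps <- 1e-6
  for (nm in names(params)) {
    numg <- params[[nm]]
    for (i in seq_along(numg)) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      numg[i] <- (wristrf:::mlp_loss_grad(up, x, y, l2)$loss -
                    wristrf:::mlp_loss_grad(dn, x, y, l2)$loss) / (2 * eps)
    }
    denom <- pmax(abs(numg), 1e-3)
    expect_lt(max(abs(lg$grad[[nm]] - numg) / denom), 1e-5)
  }
})

test_that("a linearly separable toy set is learned perfectly", {
  # oracle first: the set is separable by a threshold on feature 1
  x <- cbind(c(seq(1, 2, length.out = 10), seq(-2, -1, length.out = 10)),
             rep(c(0.3, -0.2), 10))
  y <- rep(c("group1_osteo", "group2_healthy"), each = 10)
  threshold_acc <- max(vapply(sort(x[, 1]), function(th) {
    mean((x[, 1] >= th) == (y == "group1_osteo"))
  }, numeric(1)))
  expect_equal(threshold_acc, 1)
  model <- mlp_train(x, y, mlp_config(2, n_hidden = 4, seed = 2))
  pred <- predict(model, x)
  expect_equal(mean(pred$label == y), 1)
})

test_that("shuffled labels train to chance-level validation accuracy", {
  co <- simulate_cohort(sim_params(n_group1 = 20, n_group2 = 30,
                                   effect_amplitude = 0.5, seed = 17))
  ac <- assemble_cohort(co, feature_recipe("complex_reim", "separate", TRUE))
  accs <- vapply(1:10, function(seed) {
    perm <- with(list(), {set.seed(seed * 7L); sample(length(ac$y))})
    y_shuf <- ac$y[perm]
    train <- seq_len(70)
    model <- mlp_train(ac$x[train, ], y_shuf[train],
                       mlp_config(ncol(ac$x), epochs = 200, seed = seed))
    mean(predict(model, ac$x[-train, ])$label == y_shuf[-train])
  }, numeric(1))
  majority <- max(table(ac$y)) / length(ac$y)
  expect_lt(abs(mean(accs) - majority), 0.15)
})

test_that("training and inference are deterministic given the seed", {
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("group1_osteo", "group2_healthy"), 10)
  cfg <- mlp_config(3, n_hidden = 2, epochs = 50, seed = 6)
  m1 <- mlp_train(x, y, cfg)
  m2 <- mlp_train(x, y, cfg)
  expect_identical(m1$params, m2$params)
  p1 <- predict(m1, x)
  expect_identical(p1, predict(m1, x))
  expect_equal(unname(rowSums(p1$prob)), rep(1, 20), tolerance = 1e-9)
})

test_that("duplicating every training row leaves the decision function unchanged", {
  set.seed(41)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("group1_osteo", "group2_healthy"), 10)
  cfg <- mlp_config(3, n_hidden = 2, epochs = 200, dropout_rate = 0, seed = 8)
  m1 <- mlp_train(x, y, cfg)
  m2 <- mlp_train(rbind(x, x), c(y, y), cfg)
  grid <- matrix(rnorm(30), 10, 3)
  expect_equal(predict(m2, grid)$prob, predict(m1, grid)$prob,
               tolerance = 1e-6)
})

test_that("symmetric zero logits resolve ties to the osteo group", {
  m <- mlp_build(mlp_config(402, seed = 1))
  m$params$W2[] <- 0
  m$params$b2[] <- 0
  pred <- predict(m, matrix(rnorm(402), 1))
  expect_equal(unname(pred$prob[1, ]), c(0.5, 0.5))
  expect_identical(pred$label, "group1_osteo")
})

test_that("guard rails: bad inputs are refused", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c("group1_osteo", "group2_healthy"), 5)
  cfg <- mlp_config(2, n_hidden = 2, epochs = 5)
  bad <- x; bad[1, 1] <- NaN
  expect_error(mlp_train(bad, y, cfg), "NaN/Inf")
  expect_error(mlp_train(x, rep("group1_osteo", 10), cfg), "both classes")
  m <- mlp_train(x, y, cfg)
  expect_error(predict(m, matrix(0, 1, 3)), "expects 2")
})

test_that("a trained model survives a save/load round trip", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("group1_osteo", "group2_healthy"), 10)
  m <- mlp_train(x, y, mlp_config(2, n_hidden = 3, epochs = 20, seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(m, path)
  back <- load_mlp(path)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_equal(predict(back, x)$prob, predict(m, x)$prob, tolerance = 1e-12)
})
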