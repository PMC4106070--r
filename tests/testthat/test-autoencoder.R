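# Autoencoder forward maps, cost terms, gradients and training behaviour.

test_that("encode and decode are sigmoid affine maps", {
  p <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
            W2 = matrix(0, 4, 3), b2 = rep(0, 4))
  expect_equal(encode(rep(0.3, 4), p), rep(0.5, 3))
  expect_equal(decode(rep(0.9, 3), p), rep(0.5, 4))

  p1 <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0)
  expect_equal(encode(0, p1), 0.5)

  set.seed(1)
  pr <- rsae:::init_ae_params(6, 4, seed = 2)
  h <- encode(matrix(runif(30), 5, 6), pr)
  expect_true(all(h > 0 & h < 1))
  expect_equal(dim(h), c(5L, 4L))
})

test_that("MSE loss matches its closed form", {
  expect_equal(mse_loss(matrix(1, 2, 3), matrix(1, 2, 3)), 0)
  expect_equal(mse_loss(matrix(0), matrix(1)), 0.5)
  expect_equal(mse_loss(rbind(0, 0), rbind(1, 0)), 0.25)
})

test_that("Gaussian kernel follows its closed form", {
  expect_equal(gaussian_kernel(0, 0.05), 1 / (sqrt(2 * pi) * 0.05))
  expect_equal(gaussian_kernel(0, 0.05), 7.9788456, tolerance = 1e-6)
  set.seed(3)
  u <- rnorm(20)
  expect_equal(gaussian_kernel(u, 0.3), gaussian_kernel(-u, 0.3))
  expect_equal(gaussian_kernel(3 * 0.05, 0.05) / gaussian_kernel(0, 0.05),
               exp(-4.5))
  expect_equal(gaussian_kernel(1, 2, normalize = FALSE), exp(-1 / 8))
})

test_that("correntropy estimate averages kernel values and suppresses outliers", {
  set.seed(8)
  x <- runif(30); y <- runif(30)
  sigma <- 0.2
  expect_equal(correntropy_estimate(x, x, sigma), kernel_peak(sigma))
  manual <- mean(vapply(seq_along(x), function(i) {
    kernel_peak(sigma) * exp(-(x[i] - y[i])^2 / (2 * sigma^2))
  }, numeric(1)))
  expect_equal(correntropy_estimate(x, y, sigma), manual, tolerance = 1e-12)

  # an outlier at 100 sigma contributes essentially nothing
  expect_lt(gaussian_kernel(100 * sigma, sigma) / kernel_peak(sigma), 1e-10)
})

test_that("MCC loss matches a brute-force double loop and is bounded", {
  sigma <- 0.05
  X <- matrix(runif(784), 1, 784)
  expect_equal(mcc_loss(X, X, sigma), 784 * kernel_peak(sigma))
  expect_equal(mcc_loss(X, X, sigma), 6255.42, tolerance = 1e-4)

  set.seed(12)
  A <- matrix(runif(12), 3, 4); B <- matrix(runif(12), 3, 4)
  expect_equal(mcc_loss(A, B, 0.1), brute_mcc(A, B, 0.1), tolerance = 1e-12)

  # one huge error reduces the loss by at most kernel_peak / n
  Y <- X
  Y[1, 1] <- 1e6
  drop_amt <- mcc_loss(X, X, sigma) - mcc_loss(X, Y, sigma)
  expect_lte(drop_amt, kernel_peak(sigma) + 1e-9)
  expect_gt(drop_amt, 0)
})

test_that("sparsity penalty is a scaled Bernoulli KL divergence", {
  H <- matrix(0.1, 5, 3)
  expect_equal(sparsity_penalty(H, rho = 0.1, beta = 3), 0)
  h1 <- matrix(0.2, 4, 1)
  expect_equal(sparsity_penalty(h1, 0.1, 3),
               3 * (0.1 * log(0.5) + 0.9 * log(0.9 / 0.8)))
  expect_equal(sparsity_penalty(h1, 0.1, 3), 0.110071, tolerance = 1e-5)
  set.seed(2)
  Hr <- matrix(runif(40, 0.05, 0.95), 8, 5)
  expect_gt(sparsity_penalty(Hr, 0.1, 3), 0)
  # saturated activations are clamped, not NaN
  expect_true(is.finite(sparsity_penalty(matrix(1, 3, 2), 0.1, 3)))
})

test_that("weight decay penalises squared weights only", {
  expect_equal(weight_decay(matrix(0, 2, 2), matrix(0, 2, 2), 0.003), 0)
  expect_equal(weight_decay(matrix(c(1, 2), 1, 2),
                            matrix(c(2, 1), 2, 1), 0.003), 0.015)
  set.seed(6)
  W1 <- matrix(rnorm(6), 2, 3); W2 <- matrix(rnorm(6), 3, 2)
  expect_equal(weight_decay(-W1, -W2, 0.01), weight_decay(W1, W2, 0.01))
})

test_that("composite costs equal the sum of their parts", {
  set.seed(10)
  X <- matrix(runif(8 * 6), 8, 6)
  p <- rsae:::init_ae_params(6, 4, seed = 3)
  for (norm in c(TRUE, FALSE)) {
    cm <- ae_config("MCC", sigma = 0.05, kernel_norm = norm, seed = 3)
    H <- encode(X, p); Y <- decode(H, p)
    expect_equal(rsae_cost(p, X, cm),
                 -mcc_loss(X, Y, cm$sigma, norm) +
                   weight_decay(p$W1, p$W2, cm$lambda) +
                   sparsity_penalty(H, cm$rho, cm$beta),
                 tolerance = 1e-14)
  }
  cs <- ae_config("MSE", seed = 3)
  H <- encode(X, p); Y <- decode(H, p)
  expect_equal(ssae_cost(p, X, cs),
               mse_loss(X, Y) + weight_decay(p$W1, p$W2, cs$lambda) +
                 sparsity_penalty(H, cs$rho, cs$beta),
               tolerance = 1e-14)
  expect_equal(brute_weight_decay(p$W1, p$W2, 0.003),
               weight_decay(p$W1, p$W2, 0.003), tolerance = 1e-14)
})

test_that("analytic gradients match central finite differences", {
  set.seed(21)
  X <- matrix(runif(12 * 7), 12, 7)
  p <- rsae:::init_ae_params(7, 4, seed = 4)
  theta <- rsae:::flatten_ae(p)
  for (cfg in list(ae_config("MCC", sigma = 0.05, seed = 4),
                   ae_config("MCC", sigma = 0.05, kernel_norm = TRUE, seed = 4),
                   ae_config("MSE", seed = 4))) {
    fn <- function(th) rsae:::ae_cost(rsae:::unflatten_ae(th, 7, 4), X, cfg)
    ga <- rsae:::flatten_ae(cost_gradient(p, X, cfg))
    expect_lt(grad_rel_err(ga, finite_diff_grad(fn, theta)), 1e-6)
  }
  # weight-decay block of the gradient is exactly lambda * W at zero error
  cfg0 <- ae_config("MSE", lambda = 0.01, beta = 0, seed = 1)
  pid <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
              W2 = matrix(0.5, 2, 2), b2 = c(0, 0))
  Xc <- matrix(plogis(0.5 * plogis(0) * 2), 4, 2)  # forward fixed point
  g <- cost_gradient(pid, Xc, cfg0)
  expect_equal(g$W2, 0.01 * pid$W2, tolerance = 1e-12)  # zero-error stationarity
  expect_equal(g$b2, c(0, 0), tolerance = 1e-12)
  expect_error(cost_gradient(pid, matrix(0.5, 2, 5), cfg0), "width")
})

test_that("training is deterministic, monotone and recovers low-rank structure", {
  set.seed(30)
  z1 <- runif(200); z2 <- runif(200)
  X <- 0.15 + 0.35 * outer(z1, runif(10)) + 0.35 * outer(z2, runif(10))
  X <- pmin(pmax(X, 0), 1)
  cfg <- ae_config("MSE", lambda = 0, beta = 0, max_iter = 300, seed = 5)
  p <- train_autoencoder(X, hidden = 2, cfg)
  expect_lte(attr(p, "final_cost"), attr(p, "initial_cost"))
  p2 <- train_autoencoder(X, hidden = 2, cfg)
  expect_equal(p, p2)

  Y <- decode(encode(X, p), p)
  resid <- mean((Y - X)^2)
  total_var <- mean(apply(X, 2, function(col) mean((col - mean(col))^2)))
  expect_lt(resid, 0.1 * total_var)
  # oracle: a rank-2 PCA reconstruction leaves (near) zero residual
  pc <- prcomp(X, rank. = 2)
  pca_resid <- mean((X - (pc$x %*% t(pc$rotation) +
                            matrix(pc$center, 200, 10, byrow = TRUE)))^2)
  expect_lt(pca_resid, 1e-20)

  expect_error(train_autoencoder(X * 3, 2, cfg), "\\[0, 1\\]")
})
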