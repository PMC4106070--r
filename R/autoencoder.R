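# Sparse autoencoder with a choice of reconstruction loss: maximum
# correntropy criterion (MCC, robust to impulsive outliers) or mean square
# error (MSE), plus KL sparsity and weight-decay regularisers.  Training is
# deterministic full-batch L-BFGS on the analytic gradient.

#' Autoencoder training configuration
#'
#' Defaults follow the detector's standard operating point: weight decay
#' `lambda = 0.003`, sparsity weight `beta = 3` with target `rho = 0.1`,
#' and Gaussian kernel size `sigma = 0.05` for the MCC loss (only
#' meaningful on features scaled to `[0, 1]`).
#'
#' @param loss_type `"MCC"` (robust) or `"MSE"`.
#' @param sigma Gaussian kernel size of the correntropy loss (> 0).
#' @param lambda weight-decay coefficient (>= 0).
#' @param beta sparsity penalty weight (>= 0).
#' @param rho sparsity target, the desired mean hidden activation (0, 1).
#' @param max_iter optimiser iteration cap per training stage.
#' @param seed integer seed controlling weight initialisation.
#' @param kernel_norm keep the `1/(sqrt(2 pi) sigma)` kernel normalisation
#'   constant inside the composite cost.  Off by default: the constant
#'   (about 8 at `sigma = 0.05`) would scale the correntropy term relative
#'   to the fixed sparsity and weight-decay weights, so the same
#'   `beta`/`lambda` calibration could not serve both loss types.
#' @return an `ae_config` list.
#' @export
ae_config <- function(loss_type = c("MCC", "MSE"), sigma = 0.05,
                      lambda = 0.003, beta = 3, rho = 0.1,
                      max_iter = 400L, seed = 1L, kernel_norm = FALSE) {
  loss_type <- match.arg(loss_type)
  stopifnot(lambda >= 0, beta >= 0, rho > 0, rho < 1, max_iter >= 1)
  if (loss_type == "MCC" && (!is.numeric(sigma) || sigma <= 0)) {
    stop_rsae("sigma must be positive for the MCC loss")
  }
  structure(list(loss_type = loss_type, sigma = sigma, lambda = lambda,
                 beta = beta, rho = rho, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), kernel_norm = isTRUE(kernel_norm)),
            class = "ae_config")
}

# Symmetric uniform initialisation in +/- sqrt(6 / (fan_in + fan_out));
# seeded and independent of the loss type.  When the training data are
# supplied, the decoder bias starts at the logit of the per-feature means,
# so initial reconstructions sit on the data marginals instead of 0.5 -
# essential for the correntropy loss, whose gradient vanishes for
# residuals much larger than sigma.
init_ae_params <- function(d, h, seed = NULL, X = NULL) {
  with_seed(seed, {
    r1 <- sqrt(6 / (d + h))
    b2 <- if (is.null(X)) rep(0, d) else {
      qlogis(pmin(pmax(colMeans(as_row_matrix(X)), 0.01), 0.99))
    }
    list(W1 = matrix(runif(h * d, -r1, r1), h, d),
         b1 = rep(0, h),
         W2 = matrix(runif(d * h, -r1, r1), d, h),
         b2 = b2)
  })
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Encode inputs to hidden activations
#'
#' Componentwise sigmoid of the affine map `W1 x + b1`.
#'
#' @param x length-d vector or n x d matrix of inputs in `[0, 1]`.
#' @param p autoencoder parameters (`W1`, `b1`, `W2`, `b2`).
#' @return hidden activations in `(0, 1)`, matching the input shape.
#' @export
encode <- function(x, p) {
  vec <- !is.matrix(x)
  h <- plogis(tcrossprod(as_row_matrix(x), p$W1) +
                matrix(p$b1, nrow = NROW(as_row_matrix(x)), ncol = length(p$b1),
                       byrow = TRUE))
  if (vec) drop(h) else h
}

#' Decode hidden activations to reconstructions
#'
#' Componentwise sigmoid of the affine map `W2 x' + b2`.
#'
#' @param xp length-h vector or n x h matrix of hidden activations.
#' @inheritParams encode
#' @return reconstructions in `(0, 1)`, matching the input shape.
#' @export
decode <- function(xp, p) {
  vec <- !is.matrix(xp)
  y <- plogis(tcrossprod(as_row_matrix(xp), p$W2) +
                matrix(p$b2, nrow = NROW(as_row_matrix(xp)), ncol = length(p$b2),
                       byrow = TRUE))
  if (vec) drop(y) else y
}

#' Mean square reconstruction error
#'
#' `(1/n) sum_i 0.5 * ||y_i - x_i||^2`; zero iff the reconstruction is
#' perfect.
#'
#' @param X n x d inputs.
#' @param Y n x d reconstructions.
#' @return nonnegative scalar.
#' @export
mse_loss <- function(X, Y) {
  X <- as_row_matrix(X); Y <- as_row_matrix(Y)
  stopifnot(all(dim(X) == dim(Y)))
  sum((Y - X)^2) / (2 * nrow(X))
}

#' Gaussian kernel
#'
#' `kappa_sigma(u) = exp(-u^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`.
#'
#' @param u numeric vector of differences.
#' @param sigma kernel size (> 0).
#' @param normalize include the `1/(sqrt(2 pi) sigma)` constant.
#' @return kernel values (> 0), maximal at `u = 0`.
#' @export
gaussian_kernel <- function(u, sigma, normalize = TRUE) {
  stopifnot(sigma > 0)
  k <- exp(-u^2 / (2 * sigma^2))
  if (normalize) k / (sqrt(2 * pi) * sigma) else k
}

#' Sample estimate of the correntropy of two variables
#'
#' `(1/n) sum_i kappa_sigma(x_i - y_i)`; bounded above by the kernel peak
#' `kappa_sigma(0)`, attained iff the samples coincide.
#'
#' @param x,y numeric vectors of equal length.
#' @inheritParams gaussian_kernel
#' @return scalar in `(0, kappa_sigma(0)]`.
#' @export
correntropy_estimate <- function(x, y, sigma, normalize = TRUE) {
  if (length(x) != length(y)) stop_rsae("x and y must have equal length")
  mean(gaussian_kernel(x - y, sigma, normalize))
}

#' Correntropy reconstruction objective (to be maximised)
#'
#' `J_MCC = (1/n) sum_i sum_j kappa_sigma(x_ij - y_ij)`: the kernel values
#' of all d components are summed per sample and averaged over samples.
#' Any single component, however badly reconstructed, contributes at most
#' `kappa_sigma(0) / n` - the bounded-influence property that makes the
#' robust autoencoder insensitive to outliers.
#'
#' @param X n x d inputs.
#' @param Y n x d reconstructions.
#' @inheritParams gaussian_kernel
#' @return scalar in `(0, d * kappa_sigma(0)]`, maximal iff `Y = X`.
#' @export
mcc_loss <- function(X, Y, sigma, normalize = TRUE) {
  X <- as_row_matrix(X); Y <- as_row_matrix(Y)
  stopifnot(all(dim(X) == dim(Y)))
  sum(gaussian_kernel(X - Y, sigma, normalize)) / nrow(X)
}

#' KL sparsity penalty on mean hidden activations
#'
#' With `rho_hat_i` the mean activation of hidden unit i over the batch
#' (clamped away from 0 and 1 by 1e-8), the penalty is
#' `beta * sum_i KL(rho || rho_hat_i)` for Bernoulli KL divergence.
#'
#' @param hidden n x h matrix of hidden activations.
#' @param rho sparsity target in (0, 1).
#' @param beta penalty weight (>= 0).
#' @return nonnegative scalar, zero iff every `rho_hat_i = rho`.
#' @export
sparsity_penalty <- function(hidden, rho, beta) {
  hidden <- as_row_matrix(hidden)
  rho_hat <- pmin(pmax(colMeans(hidden), 1e-8), 1 - 1e-8)
  beta * sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

#' Weight-decay penalty
#'
#' `(lambda / 2) * (sum W1^2 + sum W2^2)`; biases are not penalised.
#'
#' @param W1,W2 weight matrices.
#' @param lambda decay coefficient (>= 0).
#' @return nonnegative scalar.
#' @export
weight_decay <- function(W1, W2, lambda) {
  lambda / 2 * (sum(W1^2) + sum(W2^2))
}

ae_forward <- function(p, X) {
  H <- encode(X, p)
  list(H = as_row_matrix(H), Y = as_row_matrix(decode(H, p)))
}

#' Robust (MCC) autoencoder cost
#'
#' Forward-propagates `X` and returns
#' `-J_MCC + J_weight + J_sparse`; lower is better.
#'
#' @param p autoencoder parameters.
#' @param X n x d training matrix with entries in `[0, 1]`.
#' @param config an [ae_config()] with `loss_type = "MCC"`.
#' @return scalar cost.
#' @export
rsae_cost <- function(p, X, config) {
  stopifnot(config$loss_type == "MCC")
  fw <- ae_forward(p, as_row_matrix(X))
  -mcc_loss(X, fw$Y, config$sigma, config$kernel_norm) +
    weight_decay(p$W1, p$W2, config$lambda) +
    sparsity_penalty(fw$H, config$rho, config$beta)
}

#' Standard (MSE) autoencoder cost
#'
#' `J_MSE + J_weight + J_sparse`; lower is better.
#'
#' @inheritParams rsae_cost
#' @param config an [ae_config()] with `loss_type = "MSE"`.
#' @return scalar cost.
#' @export
ssae_cost <- function(p, X, config) {
  stopifnot(config$loss_type == "MSE")
  fw <- ae_forward(p, as_row_matrix(X))
  mse_loss(X, fw$Y) +
    weight_decay(p$W1, p$W2, config$lambda) +
    sparsity_penalty(fw$H, config$rho, config$beta)
}

ae_cost <- function(p, X, config) {
  if (config$loss_type == "MCC") rsae_cost(p, X, config)
  else ssae_cost(p, X, config)
}

#' Analytic gradient of the autoencoder cost
#'
#' Backpropagation through the sigmoid encoder/decoder for the selected
#' objective.  For the MCC loss each componentwise error signal is
#' reweighted by `exp(-(x - y)^2 / (2 sigma^2))`, so grossly
#' mis-reconstructed (outlying) components contribute vanishing gradient;
#' the sparsity gradient flows through the batch-mean activations.
#'
#' @param p autoencoder parameters.
#' @param X n x d training matrix.
#' @param config an [ae_config()].
#' @return list shaped like `p` (`W1`, `b1`, `W2`, `b2`).
#' @export
cost_gradient <- function(p, X, config) {
  X <- as_row_matrix(X)
  if (ncol(X) != ncol(p$W1)) stop_rsae("input width does not match W1")
  n <- nrow(X)
  fw <- ae_forward(p, X)
  H <- fw$H; Y <- fw$Y
  E <- Y - X
  if (config$loss_type == "MCC") {
    cnorm <- if (config$kernel_norm) 1 / (sqrt(2 * pi) * config$sigma) else 1
    dY <- (cnorm / config$sigma^2) * E * exp(-E^2 / (2 * config$sigma^2)) / n
  } else {
    dY <- E / n
  }
  delta2 <- dY * Y * (1 - Y)
  gW2 <- crossprod(delta2, H) + config$lambda * p$W2
  gb2 <- colSums(delta2)
  back <- delta2 %*% p$W2
  rho_raw <- colMeans(H)
  active <- rho_raw > 1e-8 & rho_raw < 1 - 1e-8
  rho_hat <- pmin(pmax(rho_raw, 1e-8), 1 - 1e-8)
  dsparse <- config$beta * (-config$rho / rho_hat +
                              (1 - config$rho) / (1 - rho_hat)) / n
  dsparse[!active] <- 0
  delta1 <- (back + matrix(dsparse, n, length(dsparse), byrow = TRUE)) *
    H * (1 - H)
  gW1 <- crossprod(delta1, X) + config$lambda * p$W1
  gb1 <- colSums(delta1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

flatten_ae <- function(p) c(p$W1, p$b1, p$W2, p$b2)

unflatten_ae <- function(theta, d, h) {
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  list(W1 = matrix(take(h * d), h, d), b1 = take(h),
       W2 = matrix(take(d * h), d, h), b2 = take(d))
}

#' Train one autoencoder by deterministic full-batch optimisation
#'
#' Weights are initialised uniformly in `+/- sqrt(6 / (fan_in + fan_out))`
#' under `config$seed`, encoder biases at zero and the decoder bias at the
#' logit of the per-feature training means (so initial reconstructions
#' match the data marginals - the correntropy loss receives no gradient
#' from residuals far beyond `sigma`, so a centred start matters).  The
#' selected cost is then minimised with L-BFGS (analytic gradient) for at
#' most `config$max_iter` iterations or to projected-gradient tolerance
#' 1e-6.  The run is fully deterministic given the data and seed, and the
#' final cost never exceeds the initial one.
#'
#' @param X n x d training matrix with rows in `[0, 1]`.
#' @param hidden number of hidden units.
#' @param config an [ae_config()].
#' @param init optional explicit initial parameters (overrides the seed).
#' @return trained parameters with attributes `initial_cost`, `final_cost`
#'   and `convergence`.
#' @export
train_autoencoder <- function(X, hidden, config, init = NULL) {
  X <- as_row_matrix(X)
  if (any(X < 0 | X > 1)) stop_rsae("training rows must lie in [0, 1]")
  d <- ncol(X)
  p0 <- init %||% init_ae_params(d, hidden, config$seed, X)
  theta0 <- flatten_ae(p0)
  fn <- function(theta) {
    v <- ae_cost(unflatten_ae(theta, d, hidden), X, config)
    if (!is.finite(v)) stop_rsae("non-finite autoencoder cost during optimisation")
    v
  }
  gr <- function(theta) {
    flatten_ae(cost_gradient(unflatten_ae(theta, d, hidden), X, config))
  }
  fit <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iter, pgtol = 1e-6,
                              factr = 1e4))
  p <- unflatten_ae(fit$par, d, hidden)
  attr(p, "initial_cost") <- fn(theta0)
  attr(p, "final_cost") <- fit$value
  attr(p, "convergence") <- fit$convergence
  p
}
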