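# Independent brute-force oracles and small fixtures used across tests.
# The oracles deliberately use plain loops and closed forms, never the
# package's vectorised implementations.

kernel_peak <- function(sigma, normalize = TRUE) {
  if (normalize) 1 / (sqrt(2 * pi) * sigma) else 1
}

brute_mse <- function(X, Y) {
  n <- nrow(X)
  total <- 0
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(ncol(X))) acc <- acc + (Y[i, j] - X[i, j])^2
    total <- total + acc / 2
  }
  total / n
}

brute_mcc <- function(X, Y, sigma, normalize = TRUE) {
  n <- nrow(X)
  c0 <- if (normalize) 1 / (sqrt(2 * pi) * sigma) else 1
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(X))) {
      u <- X[i, j] - Y[i, j]
      total <- total + c0 * exp(-u^2 / (2 * sigma^2))
    }
  }
  total / n
}

brute_sparsity <- function(H, rho, beta) {
  total <- 0
  for (j in seq_len(ncol(H))) {
    rh <- mean(H[, j])
    rh <- min(max(rh, 1e-8), 1 - 1e-8)
    total <- total + rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh))
  }
  beta * total
}

brute_weight_decay <- function(W1, W2, lambda) {
  total <- 0
  for (w in c(as.vector(W1), as.vector(W2))) total <- total + w^2
  lambda / 2 * total
}

# Central finite-difference gradient of a scalar function of a vector.
finite_diff_grad <- function(fn, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1L))
}

grad_rel_err <- function(g1, g2) {
  sqrt(sum((g1 - g2)^2)) / max(sqrt(sum(g1^2)) + sqrt(sum(g2^2)),
                               .Machine$double.eps)
}

# Labelled placeholder segments (1-sample data) for split logic tests.
fake_segments <- function(n_seizure, n_nonseizure) {
  mk <- function(label, i) {
    structure(list(data = matrix(i, 1, 2), label = label, start_s = i),
              class = "eeg_segment")
  }
  c(lapply(seq_len(n_seizure), function(i) mk("seizure", i)),
    lapply(seq_len(n_nonseizure), function(i) mk("nonseizure", i)))
}

# Small, quick synthetic dataset used by several module tests.
tiny_dataset <- function(seed = 1L, n_seizure = 30L, n_nonseizure = 30L,
                         n_channels = 4L, ...) {
  sc <- synth_config(n_channels = n_channels, seed = seed, ...)
  list(config = sc,
       segments = make_labeled_dataset(sc, n_seizure, n_nonseizure))
}
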