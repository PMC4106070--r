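# Layer-wise pretraining of stacked autoencoders, softmax classification
# head, and supervised joint fine-tuning by backpropagation.

CLASS_LEVELS <- c("nonseizure", "seizure")   # column/row order everywhere

new_stacked_net <- function(layers, softmax = NULL, layer_sizes) {
  structure(list(layers = layers, softmax = softmax,
                 layer_sizes = layer_sizes, classes = CLASS_LEVELS),
            class = "stacked_net")
}

#' @export
print.stacked_net <- function(x, ...) {
  cat(sprintf("<stacked_net> encoder %s%s\n",
              paste(x$layer_sizes, collapse = " -> "),
              if (is.null(x$softmax)) " (no softmax head)"
              else sprintf(" -> softmax(%d)", nrow(x$softmax$W))))
  invisible(x)
}

encoder_forward <- function(net, X, depth = length(net$layers)) {
  A <- as_row_matrix(X)
  if (depth == 0L) return(A)
  for (l in seq_len(depth)) {
    W <- net$layers[[l]]$W
    A <- plogis(tcrossprod(A, W) +
                  matrix(net$layers[[l]]$b, nrow(A), nrow(W), byrow = TRUE))
  }
  A
}

#' Pretrain a stacked autoencoder layer by layer
#'
#' The first autoencoder is trained on `X`; its hidden activations become
#' the training input of the next, and so on.  Encoder halves are stacked,
#' decoder halves discarded.  Per-layer seeds are derived from
#' `config$seed` so the whole stack is reproducible.
#'
#' @param X n x d training matrix with rows in `[0, 1]`.
#' @param layer_sizes integer vector starting at d, e.g. `c(784, 50, 10)`.
#' @param config an [ae_config()].
#' @return a `stacked_net` without a softmax head.
#' @export
pretrain_stack <- function(X, layer_sizes, config) {
  X <- as_row_matrix(X)
  stopifnot(length(layer_sizes) >= 2L, layer_sizes[1L] == ncol(X))
  seeds <- derive_seeds(config$seed, length(layer_sizes) - 1L)
  layers <- vector("list", length(layer_sizes) - 1L)
  A <- X
  for (l in seq_along(layers)) {
    cfg_l <- config
    cfg_l$seed <- seeds[l]
    p <- train_autoencoder(A, layer_sizes[l + 1L], cfg_l)
    layers[[l]] <- list(W = p$W1, b = p$b1)
    A <- encode(A, p)
  }
  new_stacked_net(layers, softmax = NULL, layer_sizes = layer_sizes)
}

init_softmax <- function(s_top, k = 2L, seed = NULL) {
  with_seed(seed, {
    r <- sqrt(6 / (s_top + k))
    list(W = matrix(runif(k * s_top, -r, r), k, s_top), b = rep(0, k))
  })
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Class posteriors and labels from a stacked network
#'
#' Forward pass through the encoder stack and softmax head.  Rows of the
#' posterior matrix are nonnegative and sum to one; `predict_labels`
#' takes the argmax, breaking exact ties toward `"nonseizure"`
#' (a conservative alarm policy).
#'
#' @param net a `stacked_net` with a softmax head.
#' @param X n x d input matrix.
#' @return `softmax_predict_proba`: n x 2 matrix with columns
#'   `nonseizure`, `seizure`; `predict_labels`: character vector.
#' @export
softmax_predict_proba <- function(net, X) {
  stopifnot(inherits(net, "stacked_net"))
  if (is.null(net$softmax)) stop_rsae("network has no softmax head yet")
  A <- encoder_forward(net, X)
  logits <- tcrossprod(A, net$softmax$W) +
    matrix(net$softmax$b, nrow(A), length(net$softmax$b), byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- net$classes
  p
}

#' @rdname softmax_predict_proba
#' @param tie_break class returned on exact posterior ties.
#' @export
predict_labels <- function(net, X, tie_break = "nonseizure") {
  p <- softmax_predict_proba(net, X)
  ord <- c(tie_break, setdiff(net$classes, tie_break))
  p <- p[, ord, drop = FALSE]
  ord[max.col(p, ties.method = "first")]
}

label_onehot <- function(labels, classes = CLASS_LEVELS) {
  labels <- as.character(labels)
  if (!all(labels %in% classes)) stop_rsae("unknown class label")
  t(vapply(labels, function(l) as.numeric(classes == l),
           numeric(length(classes))))
}

# Cross-entropy + weight-decay objective over (optionally) the whole stack.
# `scope` = "softmax" freezes the encoder (used to train the head alone);
# "all" is joint fine-tuning.
finetune_objective <- function(net, X, Tmat, lambda, scope = "all") {
  n_layers <- length(net$layers)
  function(theta) {
    nt <- unflatten_net(theta, net, scope)
    A <- as_row_matrix(X)
    acts <- vector("list", n_layers + 1L)
    acts[[1L]] <- A
    for (l in seq_len(n_layers)) {
      A <- plogis(tcrossprod(A, nt$layers[[l]]$W) +
                    matrix(nt$layers[[l]]$b, nrow(A),
                           length(nt$layers[[l]]$b), byrow = TRUE))
      acts[[l + 1L]] <- A
    }
    logits <- tcrossprod(A, nt$softmax$W) +
      matrix(nt$softmax$b, nrow(A), length(nt$softmax$b), byrow = TRUE)
    P <- softmax_rows(logits)
    n <- nrow(A)
    ce <- -sum(Tmat * log(pmax(P, 1e-300))) / n
    wsum <- sum(nt$softmax$W^2)
    if (scope == "all") {
      wsum <- wsum + sum(vapply(nt$layers, function(l) sum(l$W^2), numeric(1L)))
    }
    cost <- ce + lambda / 2 * wsum
    # gradient
    delta <- (P - Tmat) / n
    gsW <- crossprod(delta, A) + lambda * nt$softmax$W
    gsb <- colSums(delta)
    grads <- list(softmax = list(W = gsW, b = gsb), layers = NULL)
    if (scope == "all") {
      glayers <- vector("list", n_layers)
      back <- delta %*% nt$softmax$W
      for (l in rev(seq_len(n_layers))) {
        Al <- acts[[l + 1L]]
        dl <- back * Al * (1 - Al)
        glayers[[l]] <- list(W = crossprod(dl, acts[[l]]) +
                               lambda * nt$layers[[l]]$W,
                             b = colSums(dl))
        back <- dl %*% nt$layers[[l]]$W
      }
      grads$layers <- glayers
    }
    list(value = cost, grad = flatten_net_grads(grads, scope))
  }
}

flatten_net <- function(net, scope = "all") {
  parts <- list()
  if (scope == "all") {
    for (l in net$layers) parts <- c(parts, list(l$W, l$b))
  }
  c(unlist(parts, use.names = FALSE), net$softmax$W, net$softmax$b)
}

flatten_net_grads <- function(grads, scope) {
  parts <- list()
  if (scope == "all") {
    for (l in grads$layers) parts <- c(parts, list(l$W, l$b))
  }
  c(unlist(parts, use.names = FALSE), grads$softmax$W, grads$softmax$b)
}

unflatten_net <- function(theta, net, scope = "all") {
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  layers <- net$layers
  if (scope == "all") {
    for (l in seq_along(layers)) {
      W <- layers[[l]]$W
      layers[[l]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
      layers[[l]]$b <- take(length(layers[[l]]$b))
    }
  }
  Ws <- net$softmax$W
  softmax <- list(W = matrix(take(length(Ws)), nrow(Ws), ncol(Ws)),
                  b = take(length(net$softmax$b)))
  list(layers = layers, softmax = softmax)
}

run_lbfgs <- function(theta0, objective, max_iter) {
  cache <- new.env(parent = emptyenv())
  fn <- function(theta) {
    res <- objective(theta)
    if (!is.finite(res$value)) stop_rsae("non-finite cost during optimisation")
    cache$theta <- theta
    cache$grad <- res$grad
    res$value
  }
  gr <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(cache$grad)
    }
    objective(theta)$grad
  }
  optim(theta0, fn, gr, method = "L-BFGS-B",
        control = list(maxit = max_iter, pgtol = 1e-6, factr = 1e4))
}

#' Attach and train a softmax head on frozen pretrained features
#'
#' Minimises mean cross-entropy plus weight decay over the softmax
#' parameters only; the encoder stack is untouched.  This is the detector
#' "before fine-tuning".
#'
#' @param net a pretrained `stacked_net`.
#' @param X n x d training inputs.
#' @param labels character vector of `"seizure"` / `"nonseizure"`.
#' @param config an [ae_config()] supplying `lambda`, `max_iter`, `seed`.
#' @return the network with a trained softmax head.
#' @export
train_softmax <- function(net, X, labels, config) {
  stopifnot(inherits(net, "stacked_net"))
  s_top <- utils::tail(net$layer_sizes, 1L)
  net$softmax <- init_softmax(s_top, length(net$classes),
                              seed = derive_seeds(config$seed + 1L, 1L))
  Tmat <- label_onehot(labels, net$classes)
  obj <- finetune_objective(net, X, Tmat, config$lambda, scope = "softmax")
  fit <- run_lbfgs(flatten_net(net, "softmax"), obj, config$max_iter)
  upd <- unflatten_net(fit$par, net, "softmax")
  net$softmax <- upd$softmax
  net
}

#' Jointly fine-tune the whole stacked network
#'
#' Minimises the mean softmax cross-entropy plus `lambda`-weight decay
#' over all encoder and softmax weights by full-batch L-BFGS
#' backpropagation.  Sparsity is a pretraining device and is not applied
#' here.  The training cross-entropy never exceeds its initial value.
#'
#' @param net a `stacked_net`; a missing softmax head is initialised
#'   (seeded) before optimisation.
#' @param X n x d training inputs.
#' @param labels character vector of `"seizure"` / `"nonseizure"`.
#' @param config an [ae_config()] supplying `lambda`, `max_iter`, `seed`.
#' @return the fine-tuned network with attributes `initial_cost` and
#'   `final_cost`.
#' @export
fine_tune <- function(net, X, labels, config) {
  stopifnot(inherits(net, "stacked_net"))
  if (is.null(net$softmax)) {
    s_top <- utils::tail(net$layer_sizes, 1L)
    net$softmax <- init_softmax(s_top, length(net$classes),
                                seed = derive_seeds(config$seed + 1L, 1L))
  }
  Tmat <- label_onehot(labels, net$classes)
  obj <- finetune_objective(net, X, Tmat, config$lambda, scope = "all")
  theta0 <- flatten_net(net, "all")
  fit <- run_lbfgs(theta0, obj, config$max_iter)
  upd <- unflatten_net(fit$par, net, "all")
  out <- new_stacked_net(upd$layers, upd$softmax, net$layer_sizes)
  attr(out, "initial_cost") <- obj(theta0)$value
  attr(out, "final_cost") <- fit$value
  out
}

#' Forward activations at a given depth of the stack
#'
#' `depth = 0` returns the input itself; `depth = length(net$layers)`
#' (the default) returns the top-layer feature used for classification
#' and visualisation.
#'
#' @param net a `stacked_net`.
#' @param X n x d input matrix.
#' @param depth encoder layer index to stop at.
#' @return n x `layer_sizes[depth + 1]` activation matrix.
#' @export
extract_features <- function(net, X, depth = length(net$layers)) {
  stopifnot(inherits(net, "stacked_net"),
            depth >= 0L, depth <= length(net$layers))
  encoder_forward(net, X, depth)
}
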