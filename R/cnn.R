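# Small convolutional network. Activations are 4-D arrays (H, W, B, C);
# the 3x3 convolutions and 2x2 max-pooling run in compiled kernels (src/),
# the dense head and the SGD update stay in R. All randomness goes through
# the session RNG so training is reproducible under set.seed().

#' @keywords internal
#' @noRd
cnn_backbones <- function() {
  list(small_cnn      = c(8L, 16L, 32L),
       small_cnn_wide = c(12L, 24L, 48L))
}

#' @keywords internal
#' @noRd
cnn_init <- function(input_size = 64, channels = c(8, 16, 32), n_classes = 2) {
  n_in <- 1L
  conv <- list()
  for (k in seq_along(channels)) {
    n_out <- channels[k]
    sd <- sqrt(2 / (9 * n_in))  # He initialization
    conv[[k]] <- list(
      W = array(stats::rnorm(9 * n_in * n_out, 0, sd), c(3, 3, n_in, n_out)),
      b = rep(0, n_out))
    n_in <- n_out
  }
  feat_hw <- input_size / 2^length(channels)
  stopifnot(feat_hw == round(feat_hw))
  feat <- as.integer(feat_hw^2 * n_in)
  list(conv = conv,
       dense = list(W = matrix(stats::rnorm(feat * n_classes, 0,
                                            sqrt(2 / feat)), feat, n_classes),
                    b = rep(0, n_classes)),
       input_size = as.integer(input_size), channels = as.integer(channels),
       n_classes = as.integer(n_classes))
}

#' @keywords internal
#' @noRd
conv3x3_forward <- function(x, W, b) {
  list(out = .conv3x3_fwd(x, W, b), x = x)
}

#' @keywords internal
#' @noRd
conv3x3_backward <- function(cache, W, dout) {
  .conv3x3_bwd(cache$x, W, dout)
}

#' @keywords internal
#' @noRd
maxpool2_forward <- function(x) .maxpool2_fwd(x)

#' @keywords internal
#' @noRd
maxpool2_backward <- function(cache, dout, in_dim) {
  .maxpool2_bwd(dout, cache$arg, as.integer(in_dim))
}

#' @keywords internal
#' @noRd
cnn_forward <- function(net, x, train = FALSE) {
  caches <- list()
  a <- x
  for (k in seq_along(net$conv)) {
    cf <- conv3x3_forward(a, net$conv[[k]]$W, net$conv[[k]]$b)
    r <- cf$out > 0
    a <- cf$out * r
    pf <- maxpool2_forward(a)
    if (train) caches[[k]] <- list(conv = cf, relu = r, pool = pf,
                                   pre_pool_dim = dim(a))
    a <- pf$out
  }
  d <- dim(a); B <- d[3]
  flat <- aperm(a, c(1, 2, 4, 3))
  dim(flat) <- c(prod(d[c(1, 2, 4)]), B)
  logits <- t(flat) %*% net$dense$W +
    matrix(net$dense$b, B, net$n_classes, byrow = TRUE)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(logits = logits, probs = probs, flat = flat, caches = caches,
       feat_dim = d)
}

#' @keywords internal
#' @noRd
cnn_backward <- function(net, fwd, y_onehot) {
  B <- nrow(fwd$probs)
  dlogits <- (fwd$probs - y_onehot) / B
  grads <- list(dense = list(W = fwd$flat %*% dlogits,
                             b = colSums(dlogits)),
                conv = vector("list", length(net$conv)))
  dflat <- net$dense$W %*% t(dlogits)       # feat x B
  d <- fwd$feat_dim
  da <- array(dflat, c(d[1], d[2], d[4], d[3]))
  da <- aperm(da, c(1, 2, 4, 3))
  for (k in rev(seq_along(net$conv))) {
    cache <- fwd$caches[[k]]
    da <- maxpool2_backward(cache$pool, da, cache$pre_pool_dim)
    da <- da * cache$relu
    cb <- conv3x3_backward(cache$conv, net$conv[[k]]$W, da)
    grads$conv[[k]] <- list(W = cb$dW, db = cb$db)
    da <- cb$dx
  }
  grads
}

#' @keywords internal
#' @noRd
cnn_sgd_step <- function(net, grads, vel, lr, momentum) {
  for (k in seq_along(net$conv)) {
    vel$conv[[k]]$W <- momentum * vel$conv[[k]]$W - lr * grads$conv[[k]]$W
    vel$conv[[k]]$b <- momentum * vel$conv[[k]]$b - lr * grads$conv[[k]]$db
    net$conv[[k]]$W <- net$conv[[k]]$W + vel$conv[[k]]$W
    net$conv[[k]]$b <- net$conv[[k]]$b + vel$conv[[k]]$b
  }
  vel$dense$W <- momentum * vel$dense$W - lr * grads$dense$W
  vel$dense$b <- momentum * vel$dense$b - lr * grads$dense$b
  net$dense$W <- net$dense$W + vel$dense$W
  net$dense$b <- net$dense$b + vel$dense$b
  list(net = net, vel = vel)
}

#' @keywords internal
#' @noRd
cnn_zero_velocity <- function(net) {
  list(conv = lapply(net$conv, function(l)
         list(W = array(0, dim(l$W)), b = rep(0, length(l$b)))),
       dense = list(W = matrix(0, nrow(net$dense$W), ncol(net$dense$W)),
                    b = rep(0, length(net$dense$b))))
}

#' Forward scores (probability of the positive class) for an image stack.
#' @keywords internal
#' @noRd
cnn_scores <- function(net, x, chunk = 64L) {
  n <- dim(x)[3]
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    xb <- x[, , idx, drop = FALSE]
    dim(xb) <- c(dim(x)[1], dim(x)[2], length(idx), 1L)
    out[idx] <- cnn_forward(net, xb)$probs[, 2]
  }
  out
}
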