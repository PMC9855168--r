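# Native dense/convolutional network primitives used by the song detector.
# Convolution is implemented as im2col: a precomputed sparse 0/1 matrix
# gathers every kernel patch of a (flattened) batch, turning both the
# forward pass and the gradient into plain matrix products, which keeps a
# CPU-only training loop fast at the 30 x 18 input scale this package
# works at. All layers use "valid" padding and ReLU activations; the
# output neuron is a single sigmoid trained with binary cross-entropy.

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Patch-gather plan for one convolutional layer. Input tensors of shape
# (H, W, C) are flattened column-major (i + H*(j-1) + H*W*(c-1)); the
# sparse matrix S maps a batch matrix N x (H*W*C) to N x (K * n_pos)
# patches, with kernel offset k fastest (k = dy + kh*(dx-1) + kh*kw*(c-1))
# and output position p = oi + oh*(oj-1).
conv_plan <- function(in_shape, kernel, stride, filters) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  kh <- kernel[1]; kw <- kernel[2]; sh <- stride[1]; sw <- stride[2]
  oh <- floor((H - kh) / sh) + 1L
  ow <- floor((W - kw) / sw) + 1L
  if (oh < 1L || ow < 1L)
    stop(sprintf("kernel %dx%d does not fit input %dx%dx%d", kh, kw, H, W, C),
         call. = FALSE)
  K <- kh * kw * C
  g <- expand.grid(dy = seq_len(kh), dx = seq_len(kw), c = seq_len(C),
                   oi = seq_len(oh), oj = seq_len(ow))
  i <- (g$oi - 1L) * sh + g$dy
  j <- (g$oj - 1L) * sw + g$dx
  rows <- i + H * (j - 1L) + H * W * (g$c - 1L)
  k <- g$dy + kh * (g$dx - 1L) + kh * kw * (g$c - 1L)
  p <- g$oi + oh * (g$oj - 1L)
  cols <- k + K * (p - 1L)
  S <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(H * W * C, K * oh * ow))
  list(S = S, K = K, oh = oh, ow = ow, ohow = oh * ow,
       out_shape = c(oh, ow, filters))
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Forward pass over the layer stack. X: N x (H*W*C); cov: N x 4.
# Returns probabilities and, when caches = TRUE, the per-layer
# intermediates needed by nn_backward.
nn_forward <- function(model, X, cov, training = FALSE, caches = FALSE) {
  N <- nrow(X)
  a <- X
  cc <- if (caches) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "concat") {
      if (caches) cc[[li]] <- list(n_in = ncol(a))
      a <- cbind(a, cov)
      next
    }
    w <- model$weights[[paste0("W_", ly$name)]]
    b <- model$weights[[paste0("b_", ly$name)]]
    if (ly$type == "conv") {
      P <- as.matrix(a %*% ly$S)
      dim(P) <- c(N, ly$K, ly$ohow)
      Pm <- aperm(P, c(1, 3, 2))
      dim(Pm) <- c(N * ly$ohow, ly$K)
      Z <- Pm %*% w + rep(b, each = N * ly$ohow)
      A <- relu(Z)
      if (caches) cc[[li]] <- list(Pm = Pm, Z = Z)
      dim(A) <- c(N, ly$ohow * ly$filters)
      a <- A
    } else if (ly$type == "dense") {
      Z <- a %*% w + rep(b, each = N)
      A <- relu(Z)
      mask <- NULL
      if (training && ly$dropout > 0) {
        mask <- (matrix(stats::runif(length(A)), nrow(A)) >= ly$dropout) /
          (1 - ly$dropout)
        A <- A * mask
      }
      if (caches) cc[[li]] <- list(a_in = a, Z = Z, mask = mask)
      a <- A
    } else if (ly$type == "output") {
      Z <- a %*% w + rep(b, each = N)
      if (caches) cc[[li]] <- list(a_in = a, Z = Z)
      a <- sigmoid(Z)
    }
  }
  list(prob = as.numeric(a), caches = cc)
}

# Gradients of mean binary cross-entropy w.r.t. every weight tensor.
nn_backward <- function(model, fw, X, y) {
  N <- length(y)
  grads <- list()
  delta <- matrix((fw$prob - y) / N, ncol = 1)  # dL/dz at the sigmoid
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    ca <- fw$caches[[li]]
    if (ly$type == "output") {
      grads[[paste0("W_", ly$name)]] <- crossprod(ca$a_in, delta)
      grads[[paste0("b_", ly$name)]] <- colSums(delta)
      delta <- delta %*% t(model$weights[[paste0("W_", ly$name)]])
    } else if (ly$type == "dense") {
      if (!is.null(ca$mask)) delta <- delta * ca$mask
      dZ <- delta * (ca$Z > 0)
      grads[[paste0("W_", ly$name)]] <- crossprod(ca$a_in, dZ)
      grads[[paste0("b_", ly$name)]] <- colSums(dZ)
      delta <- dZ %*% t(model$weights[[paste0("W_", ly$name)]])
    } else if (ly$type == "concat") {
      delta <- delta[, seq_len(ca$n_in), drop = FALSE]
    } else if (ly$type == "conv") {
      dA <- delta
      dim(dA) <- c(N * ly$ohow, ly$filters)
      dZ <- dA * (ca$Z > 0)
      grads[[paste0("W_", ly$name)]] <- crossprod(ca$Pm, dZ)
      grads[[paste0("b_", ly$name)]] <- colSums(dZ)
      dP <- tcrossprod(dZ, model$weights[[paste0("W_", ly$name)]])
      dim(dP) <- c(N, ly$ohow, ly$K)
      dP <- aperm(dP, c(1, 3, 2))
      dim(dP) <- c(N, ly$K * ly$ohow)
      delta <- as.matrix(dP %*% Matrix::t(ly$S))
    }
  }
  grads
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

# One Adam step; weights belonging to frozen layers are never touched.
adam_step <- function(weights, grads, state, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  frozen_keys <- c(paste0("W_", frozen), paste0("b_", frozen))
  for (k in names(grads)) {
    if (k %in% frozen_keys) next
    g <- as.numeric(grads[[k]])
    state$m[[k]][] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]][] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    weights[[k]][] <- weights[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
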