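# Low-level differentiable layer primitives. All layers are functional:
# forward returns the output plus a cache; backward consumes the cache and
# the upstream gradient and returns input/parameter gradients. Tensors are
# base-R arrays [batch, time, filters]; matrix multiplies carry the load.

#' Temporal length of a VALID (no padding) strided convolution
#'
#' @param L input length in samples (`L >= k`).
#' @param k kernel length.
#' @param s stride (>= 1).
#' @return `floor((L - k) / s) + 1`.
#' @export
conv_output_length <- function(L, k, s) {
  if (s < 1) stop("stride must be >= 1")
  if (L < k) stop("input length ", L, " is shorter than kernel ", k)
  as.integer((L - k) %/% s + 1L)
}

# im2col gather: X [B, L, Cin] -> M [B*Lout, k*Cin] (k fastest, then Cin),
# rows ordered batch-fastest then output position. The gather index is
# built output-position-fastest so the reshape to [B, Lout, k, Cin] needs
# no aperm.
conv1d_im2col <- function(X, k, s) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- conv_output_length(L, k, s)
  starts <- (seq_len(Lout) - 1L) * s
  idx <- as.vector(outer(starts, seq_len(k), `+`))  # Lout x k, col-major
  Xg <- X[, idx, , drop = FALSE]
  dim(Xg) <- c(B * Lout, k * Cin)
  list(M = Xg, B = B, L = L, Lout = Lout, Cin = Cin)
}

# W: [k*Cin, Cout], rows ordered kernel-tap fastest then input channel.
# No bias: batch normalization follows immediately.
conv1d_forward <- function(X, W, k, s) {
  g <- conv1d_im2col(X, k, s)
  Y <- g$M %*% W
  dim(Y) <- c(g$B, g$Lout, ncol(W))
  list(out = Y, cache = g)
}

conv1d_backward <- function(dY, cache, W, k, s) {
  B <- cache$B; Lout <- cache$Lout; Cin <- cache$Cin; L <- cache$L
  dim(dY) <- c(B * Lout, ncol(W))
  dW <- crossprod(cache$M, dY)
  dM <- tcrossprod(dY, W)            # [B*Lout, k*Cin]
  dim(dM) <- c(B, Lout, k, Cin)
  dX <- array(0, c(B, L, Cin))
  starts <- (seq_len(Lout) - 1L) * s
  for (t in seq_len(k)) {
    dX[, starts + t, ] <- dX[, starts + t, ] + dM[, , t, ]
  }
  list(dX = dX, dW = dW)
}

bn_init <- function(n_filters) {
  list(gamma = rep(1, n_filters), beta = rep(0, n_filters),
       running_mean = rep(0, n_filters), running_var = rep(1, n_filters))
}

# Batch normalization over (batch x time) per filter. In training mode the
# batch statistics are used and the running statistics are decayed with
# `momentum` (running <- momentum * running + (1 - momentum) * batch).
# The affine form y = a*x + b with a = gamma*invstd, b = beta - mu*a keeps
# the forward pass to a single scale-and-shift; xhat is reconstructed in
# the backward pass (training only) rather than cached.
bn_forward <- function(X, p, train, momentum = 0.99, eps = 1e-3) {
  d <- dim(X)
  N <- d[1] * d[2]
  x2 <- X; dim(x2) <- c(N, d[3])
  if (train) {
    mu <- .colMeans(x2, N, d[3])
    va <- .colMeans(x2 * x2, N, d[3]) - mu * mu
    p$running_mean <- momentum * p$running_mean + (1 - momentum) * mu
    p$running_var <- momentum * p$running_var + (1 - momentum) * va
  } else {
    mu <- p$running_mean
    va <- p$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  a <- p$gamma * invstd
  b <- p$beta - mu * a
  y <- x2 * rep(a, each = N) + rep(b, each = N)
  dim(y) <- d
  list(out = y, params = p,
       cache = list(x2 = x2, mu = mu, invstd = invstd, dims = d,
                    train = train))
}

bn_backward <- function(dY, cache, p) {
  d <- cache$dims
  N <- d[1] * d[2]
  dy <- dY; dim(dy) <- c(N, d[3])
  xhat <- (cache$x2 - rep(cache$mu, each = N)) *
    rep(cache$invstd, each = N)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  g <- rep(p$gamma * cache$invstd, each = N)
  if (cache$train) {
    dx <- g * (dy - rep(dbeta / N, each = N) -
                 xhat * rep(dgamma / N, each = N))
  } else {
    dx <- g * dy  # running stats are constants in eval mode
  }
  dim(dx) <- d
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_backward <- function(dY, cache) dY * cache

# Global average pooling over the temporal axis: [B, L, F] -> [B, F].
gap_forward <- function(X) {
  d <- dim(X)
  out <- colMeans(aperm(X, c(2, 1, 3)))
  dim(out) <- c(d[1], d[3])
  list(out = out, cache = d)
}

gap_backward <- function(dY, d) {
  dX <- array(0, d)
  sc <- dY / d[2]
  for (t in seq_len(d[2])) dX[, t, ] <- sc
  dX
}

row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)  # numerical stabilization
  E <- exp(S)
  E / rowSums(E)
}
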