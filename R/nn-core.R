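# Internal neural-network primitives.
#
# Batched activations live in "pixel-matrix" layout: a (H*W*N) x C matrix
# whose rows are ordered like an [H, W, N] array in column-major order.
# This makes a 1x1 convolution a plain matrix product, which is the critical
# path for the kernel-size-1 network variant.

# ---- layout helpers ---------------------------------------------------------

# list of H x W x C arrays -> (H*W*N) x C matrix + dims c(H, W, N)
images_to_mat <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  d <- dim(images[[1L]])
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- length(images)
  out <- matrix(0, H * W * N, C)
  for (n in seq_len(N)) {
    di <- dim(images[[n]])
    if (!all(di == d)) stop("all images in a batch must share one shape")
    out[((n - 1L) * H * W + 1L):(n * H * W), ] <- matrix(images[[n]], H * W, C)
  }
  attr(out, "dims") <- c(H, W, N)
  out
}

mat_to_array <- function(X, dims, n = 1L) {
  H <- dims[1L]; W <- dims[2L]
  C <- ncol(X)
  rows <- ((n - 1L) * H * W + 1L):(n * H * W)
  array(X[rows, ], dim = c(H, W, C))
}

# ---- convolution ------------------------------------------------------------

conv_out_size <- function(n, k, stride) {
  p <- (k - 1L) %/% 2L
  as.integer(floor((n + 2L * p - k) / stride) + 1L)
}

# strided row subsampling indices for the k = 1 fast path
.sub_idx <- function(H, W, N, stride) {
  ri <- seq(1L, H, by = stride)
  ci <- seq(1L, W, by = stride)
  base <- outer(ri, (ci - 1L) * H, "+")              # Ho x Wo within image
  idx <- as.integer(outer(as.integer(base), (seq_len(N) - 1L) * H * W, "+"))
  idx
}

# X: pixel-matrix (H*W*N) x Cin; Wm: (k*k*Cin) x Cout with rows ordered
# offset-major (spatial offset o = a + (b-1)*k slow, input channel fast is
# FALSE: within offset o the Cin channels are contiguous).
conv_forward <- function(X, dims, Wm, b, k, stride) {
  H <- dims[1L]; W <- dims[2L]; N <- dims[3L]
  Cin <- ncol(X)
  Ho <- conv_out_size(H, k, stride); Wo <- conv_out_size(W, k, stride)
  if (k == 1L) {
    M <- if (stride == 1L) X else X[.sub_idx(H, W, N, stride), , drop = FALSE]
  } else {
    p <- (k - 1L) %/% 2L
    a4 <- aperm(array(X, dim = c(H, W, N, Cin)), c(1L, 2L, 4L, 3L))
    apad <- array(0, dim = c(H + 2L * p, W + 2L * p, Cin, N))
    apad[p + seq_len(H), p + seq_len(W), , ] <- a4
    ri <- seq(1L, by = stride, length.out = Ho)
    ci <- seq(1L, by = stride, length.out = Wo)
    M <- matrix(0, Ho * Wo * N, k * k * Cin)
    for (bb in seq_len(k)) for (aa in seq_len(k)) {
      o <- aa + (bb - 1L) * k
      sl <- apad[ri + aa - 1L, ci + bb - 1L, , , drop = FALSE]
      sl <- aperm(sl, c(1L, 2L, 4L, 3L))             # Ho, Wo, N, Cin
      M[, ((o - 1L) * Cin + 1L):(o * Cin)] <- matrix(sl, Ho * Wo * N, Cin)
    }
  }
  Y <- M %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  attr(Y, "dims") <- c(Ho, Wo, N)
  list(out = Y, M = M, dims_in = c(H, W, N), dims_out = c(Ho, Wo, N))
}

conv_backward <- function(dY, cache, Wm, k, stride) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(Wm)
  H <- cache$dims_in[1L]; W <- cache$dims_in[2L]; N <- cache$dims_in[3L]
  Ho <- cache$dims_out[1L]; Wo <- cache$dims_out[2L]
  Cin <- ncol(dM) / (k * k)
  if (k == 1L) {
    if (stride == 1L) {
      dX <- dM
    } else {
      dX <- matrix(0, H * W * N, Cin)
      dX[.sub_idx(H, W, N, stride), ] <- dM
    }
  } else {
    p <- (k - 1L) %/% 2L
    dpad <- array(0, dim = c(H + 2L * p, W + 2L * p, Cin, N))
    ri <- seq(1L, by = stride, length.out = Ho)
    ci <- seq(1L, by = stride, length.out = Wo)
    for (bb in seq_len(k)) for (aa in seq_len(k)) {
      o <- aa + (bb - 1L) * k
      block <- array(dM[, ((o - 1L) * Cin + 1L):(o * Cin)],
                     dim = c(Ho, Wo, N, Cin))
      block <- aperm(block, c(1L, 2L, 4L, 3L))       # Ho, Wo, Cin, N
      dpad[ri + aa - 1L, ci + bb - 1L, , ] <-
        dpad[ri + aa - 1L, ci + bb - 1L, , , drop = FALSE] + block
    }
    dcrop <- dpad[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
    dX <- matrix(aperm(dcrop, c(1L, 2L, 4L, 3L)), H * W * N, Cin)
  }
  attr(dX, "dims") <- c(H, W, N)
  list(dX = dX, dW = dW, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(U, bn, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(U)
    v <- colMeans(U * U) - mu * mu
    v[v < 0] <- 0
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(U, 2L, mu, "-"), 2L, invstd, "*")
  Y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(out = Y, xhat = xhat, invstd = invstd, bn = bn)
}

bn_backward <- function(dY, cache, bn) {
  P <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, bn$gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dU <- sweep(t1 - t2, 2L, cache$invstd, "*")
  list(dU = dU, dgamma = dgamma, dbeta = dbeta)
}

# ---- gating (u * sigmoid(u)) ------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

gate_forward <- function(U) {
  s <- sigmoid(U)
  list(out = U * s, s = s, U = U)
}

gate_backward <- function(dY, cache) {
  dY * (cache$s * (1 + cache$U * (1 - cache$s)))
}

# ---- global average pooling -------------------------------------------------

gap_forward <- function(X, dims) {
  HW <- dims[1L] * dims[2L]; N <- dims[3L]; C <- ncol(X)
  Z <- array(X, dim = c(HW, N * C))
  matrix(colMeans(Z), N, C)
}

gap_backward <- function(dL, dims) {
  HW <- dims[1L] * dims[2L]; N <- dims[3L]
  dX <- dL[rep(seq_len(N), each = HW), , drop = FALSE] / HW
  attr(dX, "dims") <- dims
  dX
}

# ---- softmax cross-entropy --------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# labels: 0-based integer vector length N
softmax_ce <- function(logits, labels) {
  N <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(N), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dlogits = dZ / N)
}

# ---- block = conv -> batchnorm -> gate --------------------------------------

new_block <- function(Cin, Cout, k, stride) {
  fan_in <- k * k * Cin
  list(
    W = matrix(stats::rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)),
               fan_in, Cout),
    b = numeric(Cout),
    gamma = rep(1, Cout), beta = numeric(Cout),
    running_mean = numeric(Cout), running_var = rep(1, Cout),
    k = as.integer(k), stride = as.integer(stride),
    Cin = as.integer(Cin), Cout = as.integer(Cout)
  )
}

block_forward <- function(blk, X, dims, training = FALSE) {
  cv <- conv_forward(X, dims, blk$W, blk$b, blk$k, blk$stride)
  bn <- bn_forward(cv$out, blk, training)
  gt <- gate_forward(bn$out)
  attr(gt$out, "dims") <- cv$dims_out
  list(out = gt$out, dims = cv$dims_out, blk = bn$bn,
       cache = list(cv = cv, bn = bn, gt = gt))
}

block_backward <- function(blk, cache, dOut) {
  dU <- gate_backward(dOut, cache$gt)
  bb <- bn_backward(dU, cache$bn, blk)
  cb <- conv_backward(bb$dU, cache$cv, blk$W, blk$k, blk$stride)
  list(dX = cb$dX,
       grads = list(W = cb$dW, b = cb$db, gamma = bb$dgamma, beta = bb$dbeta))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.9, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# run body with a private RNG stream, restoring the caller's state after
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  body
}
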