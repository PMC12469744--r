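# Internal numerical engine for the 1-D sequence CNN.
#
# Tensors are dense base-R arrays in (N, L, C) layout (sample index fastest).
# Each conv + ReLU + max-pool block runs as one fused compiled kernel
# (src/kernels.cpp) so the full convolution map never materialises; dense
# layers are BLAS matrix products. Gradients are exact analytic backprop;
# optimisation is Adam.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Forward pass; returns p = P(label = 1) and, if keep_cache, everything the
# backward pass needs. Dropout is "inverted" so evaluation needs no rescaling.
.cnn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  arch <- model$arch
  pp <- model$params
  N <- dim(X)[1L]
  cache <- list(conv = vector("list", arch$n_conv),
                dense = vector("list", arch$n_dense_hidden))
  A <- X
  for (i in seq_len(arch$n_conv)) {
    blk <- .cpp_convpool_fw(A, pp[[paste0("c", i, ".W")]],
                            pp[[paste0("c", i, ".b")]],
                            arch$pool_width, arch$pool_stride)
    if (keep_cache)
      cache$conv[[i]] <- list(X = A, out = blk$out, arg = blk$arg)
    A <- blk$out
  }
  H <- A
  dim(H) <- c(N, prod(dim(A)[2:3]))
  for (i in seq_len(arch$n_dense_hidden)) {
    Z <- H %*% pp[[paste0("d", i, ".W")]] +
      rep(pp[[paste0("d", i, ".b")]], each = N)
    R <- pmax(Z, 0)
    mask <- NULL
    if (train && arch$dropout_rate > 0) {
      mask <- (matrix(runif(length(R)), nrow(R)) >= arch$dropout_rate) /
        (1 - arch$dropout_rate)
      R <- R * mask
    }
    if (keep_cache)
      cache$dense[[i]] <- list(X = H, relu_mask = Z > 0, drop_mask = mask)
    H <- R
  }
  z <- drop(H %*% pp$out.W) + pp$out.b
  if (keep_cache) cache$out <- list(X = H)
  list(p = .sigmoid(z), cache = if (keep_cache) cache else NULL)
}

.cnn_backward <- function(model, fw, y) {
  arch <- model$arch
  pp <- model$params
  cache <- fw$cache
  N <- length(y)
  grads <- list()
  dz <- matrix((fw$p - y) / N, ncol = 1L)    # BCE + sigmoid
  H <- cache$out$X
  grads$out.W <- crossprod(H, dz)
  grads$out.b <- sum(dz)
  dH <- dz %*% t(pp$out.W)
  for (i in rev(seq_len(arch$n_dense_hidden))) {
    cc <- cache$dense[[i]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    dZ <- dH * cc$relu_mask
    grads[[paste0("d", i, ".W")]] <- crossprod(cc$X, dZ)
    grads[[paste0("d", i, ".b")]] <- colSums(dZ)
    dH <- dZ %*% t(pp[[paste0("d", i, ".W")]])
  }
  # un-flatten into the last pooled feature map
  dA <- dH
  dim(dA) <- dim(cache$conv[[arch$n_conv]]$out)
  for (i in rev(seq_len(arch$n_conv))) {
    cc <- cache$conv[[i]]
    cb <- .cpp_convpool_bw(dA, cc$out, cc$arg, cc$X,
                           pp[[paste0("c", i, ".W")]], need_dx = i > 1L)
    grads[[paste0("c", i, ".W")]] <- cb$dW
    grads[[paste0("c", i, ".b")]] <- cb$db
    if (i > 1L) dA <- cb$dX
  }
  grads
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# chunked forward in evaluation mode, returns P(label = 1) per record
.cnn_predict_prob <- function(model, X, chunk = 512L) {
  N <- dim(X)[1L]
  p <- numeric(N)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    p[s:e] <- .cnn_forward(model, X[s:e, , , drop = FALSE])$p
  }
  p
}
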