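# Minimal multilayer-perceptron machinery shared by the DANN and the locally
# sparse network. All forward/backward passes are plain matrix algebra so that
# the gradient-reversal and stochastic-gate update rules can be implemented
# exactly as stated, and checked against finite differences.

.SELU_LAMBDA <- 1.0507009873554805
.SELU_ALPHA <- 1.6732632423543772

.actForward <- function(z, act) {
  switch(act,
    identity = z,
    relu = pmax(z, 0),
    tanh = tanh(z),
    selu = .SELU_LAMBDA * ifelse(z > 0, z, .SELU_ALPHA * (exp(z) - 1)),
    swish = z * stats::plogis(z),
    stop("unknown activation: ", act))
}

.actGrad <- function(z, act) {
  switch(act,
    identity = matrix(1, nrow(z), ncol(z)),
    relu = (z > 0) + 0,
    tanh = 1 - tanh(z)^2,
    selu = .SELU_LAMBDA * ifelse(z > 0, 1, .SELU_ALPHA * exp(z)),
    swish = { s <- stats::plogis(z); s * (1 + z * (1 - s)) },
    stop("unknown activation: ", act))
}

# layer widths: dIn -> widths[1] -> ... -> widths[K]; acts has length K.
# Weights drawn U(-1/sqrt(fanin), 1/sqrt(fanin)) from the ambient RNG stream.
.mlpInit <- function(dIn, widths, acts) {
  stopifnot(length(acts) == length(widths))
  sizes <- c(dIn, widths)
  W <- vector("list", length(widths))
  b <- vector("list", length(widths))
  for (k in seq_along(widths)) {
    lim <- 1 / sqrt(sizes[k])
    W[[k]] <- matrix(stats::runif(sizes[k] * sizes[k + 1L], -lim, lim),
                     sizes[k], sizes[k + 1L])
    b[[k]] <- numeric(sizes[k + 1L])
  }
  list(W = W, b = b, act = acts)
}

# X: n x dIn. Inverted dropout on hidden activations (never the output layer)
# when training. Returns the cache needed for backprop.
.mlpForward <- function(net, X, dropout = 0, training = FALSE) {
  nl <- length(net$W)
  A <- vector("list", nl + 1L)
  Z <- vector("list", nl)
  M <- vector("list", nl)
  A[[1L]] <- X
  for (k in seq_len(nl)) {
    Zk <- A[[k]] %*% net$W[[k]]
    Zk <- Zk + rep(net$b[[k]], each = nrow(Zk))
    Ak <- .actForward(Zk, net$act[k])
    if (training && dropout > 0 && k < nl) {
      m <- (matrix(stats::runif(length(Ak)), nrow(Ak)) >= dropout) /
        (1 - dropout)
      Ak <- Ak * m
      M[[k]] <- m
    }
    Z[[k]] <- Zk
    A[[k + 1L]] <- Ak
  }
  list(out = A[[nl + 1L]], A = A, Z = Z, M = M)
}

# dOut: gradient wrt the network output (post-activation). Returns per-layer
# weight/bias gradients and the gradient wrt the input.
.mlpBackward <- function(net, cache, dOut) {
  nl <- length(net$W)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  delta <- dOut
  dIn <- NULL
  for (k in rev(seq_len(nl))) {
    hasMask <- !is.null(cache$M[[k]])
    if (hasMask) delta <- delta * cache$M[[k]]
    # tanh/relu gradients come cheaply from the cached activation when no
    # dropout mask separates it from the pre-activation
    dZ <- if (!hasMask && net$act[k] == "tanh")
      delta * (1 - cache$A[[k + 1L]]^2)
    else if (!hasMask && net$act[k] == "relu")
      delta * (cache$Z[[k]] > 0)
    else if (net$act[k] == "identity") delta
    else delta * .actGrad(cache$Z[[k]], net$act[k])
    gW[[k]] <- crossprod(cache$A[[k]], dZ)
    gb[[k]] <- colSums(dZ)
    delta <- tcrossprod(dZ, net$W[[k]])
  }
  list(gW = gW, gb = gb, dIn = delta)
}

.softmax <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# y: 1-based class index. Mean cross-entropy over rows.
.crossEntropy <- function(P, y) {
  mean(-log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-300)))
}

.onehot <- function(y, k) {
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

# flatten a net into a parameter list (W1, b1, W2, b2, ...) ------------------

.netParams <- function(net) {
  out <- vector("list", 2L * length(net$W))
  for (k in seq_along(net$W)) {
    out[[2L * k - 1L]] <- net$W[[k]]
    out[[2L * k]] <- net$b[[k]]
  }
  out
}

.netIsWeight <- function(net) rep(c(TRUE, FALSE), length(net$W))

.setNetParams <- function(net, params) {
  for (k in seq_along(net$W)) {
    net$W[[k]] <- params[[2L * k - 1L]]
    net$b[[k]] <- params[[2L * k]]
  }
  net
}

.gradParams <- function(grads) {
  out <- vector("list", 2L * length(grads$gW))
  for (k in seq_along(grads$gW)) {
    out[[2L * k - 1L]] <- grads$gW[[k]]
    out[[2L * k]] <- grads$gb[[k]]
  }
  out
}

# optimizers -----------------------------------------------------------------

.optInit <- function(method, params) {
  zeros <- lapply(params, function(p) p * 0)
  list(method = method, t = 0L, m = zeros, v = zeros)
}

# Weight decay (L2) is added to the gradient of weight tensors only.
.optStep <- function(opt, params, grads, lr, weightDecay, isWeight) {
  if (opt$method == "adam") opt$t <- opt$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (weightDecay > 0 && isWeight[i]) g <- g + weightDecay * params[[i]]
    if (opt$method == "sgd") {
      params[[i]] <- params[[i]] - lr * g
    } else if (opt$method == "rmsprop") {
      opt$v[[i]] <- 0.9 * opt$v[[i]] + 0.1 * g^2
      params[[i]] <- params[[i]] - lr * g / sqrt(opt$v[[i]] + 1e-8)
    } else if (opt$method == "adam") {
      opt$m[[i]] <- 0.9 * opt$m[[i]] + 0.1 * g
      opt$v[[i]] <- 0.999 * opt$v[[i]] + 0.001 * g^2
      mhat <- opt$m[[i]] / (1 - 0.9^opt$t)
      vhat <- opt$v[[i]] / (1 - 0.999^opt$t)
      params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + 1e-8)
    } else stop("unknown optimizer: ", opt$method)
  }
  list(opt = opt, params = params)
}

# rescale a gradient list so its global L2 norm is at most maxNorm
.clipGrads <- function(grads, maxNorm) {
  if (!is.finite(maxNorm)) return(grads)
  g2 <- sum(vapply(grads, function(t) sum(t^2), 0))
  if (g2 > maxNorm^2) grads <- lapply(grads, function(t) t * maxNorm / sqrt(g2))
  grads
}

# minibatch index blocks for one epoch (ambient RNG shuffles)
.miniBatches <- function(n, batchSize) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batchSize))
}

# argmax with ties broken toward the lowest class index; returns 0-based
.argmax0 <- function(scores) {
  apply(scores, 1L, which.max) - 1L
}
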