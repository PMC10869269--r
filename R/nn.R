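# Minimal dense-network machinery (linear / batch-norm / ReLU layers, Adam)
# used by the alphabet learner and the E-value calibration net. Batches are
# B x d matrices; everything is deterministic given the R RNG state.

nn_linear <- function(nin, nout) {
  # He-style initialization
  list(type = "linear",
       W = matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = rep(0, nout))
}

nn_bn <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, d), beta = rep(0, d),
       running_mean = rep(0, d), running_var = rep(1, d),
       momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")

# forward pass; returns output, per-layer caches, and the net (running
# batch-norm statistics are updated when train = TRUE)
nn_forward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net))
  for (li in seq_along(net)) {
    l <- net[[li]]
    if (l$type == "linear") {
      caches[[li]] <- list(X = X)
      X <- sweep(X %*% l$W, 2, l$b, "+")
    } else if (l$type == "relu") {
      mask <- X > 0
      caches[[li]] <- list(mask = mask)
      X <- X * mask
    } else if (l$type == "bn") {
      if (train) {
        mu <- colMeans(X)
        xc <- sweep(X, 2, mu)
        v <- colMeans(xc^2)
        invstd <- 1 / sqrt(v + l$eps)
        xhat <- sweep(xc, 2, invstd, "*")
        net[[li]]$running_mean <- (1 - l$momentum) * l$running_mean +
          l$momentum * mu
        net[[li]]$running_var <- (1 - l$momentum) * l$running_var +
          l$momentum * v
      } else {
        invstd <- 1 / sqrt(l$running_var + l$eps)
        xhat <- sweep(sweep(X, 2, l$running_mean), 2, invstd, "*")
      }
      caches[[li]] <- list(xhat = xhat, invstd = invstd)
      X <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
    }
  }
  list(out = X, caches = caches, net = net)
}

# backward pass; returns gradient wrt the input and per-layer parameter grads
nn_backward <- function(net, caches, dY) {
  grads <- vector("list", length(net))
  for (li in rev(seq_along(net))) {
    l <- net[[li]]
    cc <- caches[[li]]
    if (l$type == "linear") {
      grads[[li]] <- list(W = crossprod(cc$X, dY), b = colSums(dY))
      dY <- dY %*% t(l$W)
    } else if (l$type == "relu") {
      dY <- dY * cc$mask
    } else if (l$type == "bn") {
      B <- nrow(dY)
      dxhat <- sweep(dY, 2, l$gamma, "*")
      grads[[li]] <- list(gamma = colSums(dY * cc$xhat), beta = colSums(dY))
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), "*")
      dY <- sweep(t1 - t2, 2, cc$invstd, "*")
    }
  }
  list(dX = dY, grads = grads)
}

# number of trainable parameters, optionally skipping batch-norm layers
nn_count_params <- function(net, include_bn = FALSE) {
  tot <- 0
  for (l in net) {
    if (l$type == "linear") tot <- tot + length(l$W) + length(l$b)
    if (l$type == "bn" && include_bn)
      tot <- tot + length(l$gamma) + length(l$beta)
  }
  tot
}

# ---------------------------------------------------------------------------
# Adam over an arbitrary nested list of numeric arrays

adam_init <- function() list(t = 0, m = list(), v = list())

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, character(0))
  list(params = r$p, state = list(t = t, m = r$m, v = r$v))
}

# extract / restore the trainable parameters of a net as a named nested list
nn_get_params <- function(net) {
  ps <- list()
  for (li in seq_along(net)) {
    l <- net[[li]]
    nm <- paste0("L", li)
    if (l$type == "linear") ps[[nm]] <- list(W = l$W, b = l$b)
    if (l$type == "bn") ps[[nm]] <- list(gamma = l$gamma, beta = l$beta)
  }
  ps
}

nn_set_params <- function(net, ps) {
  for (li in seq_along(net)) {
    nm <- paste0("L", li)
    if (is.null(ps[[nm]])) next
    for (f in names(ps[[nm]])) net[[li]][[f]] <- ps[[nm]][[f]]
  }
  net
}

nn_grads_as_params <- function(net, grads) {
  ps <- list()
  for (li in seq_along(net)) {
    if (is.null(grads[[li]])) next
    nm <- paste0("L", li)
    g <- grads[[li]]
    if (net[[li]]$type == "linear") ps[[nm]] <- list(W = g$W, b = g$b)
    if (net[[li]]$type == "bn") ps[[nm]] <- list(gamma = g$gamma, beta = g$beta)
  }
  ps
}
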