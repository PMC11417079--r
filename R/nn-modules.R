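# A compact layer framework for the two estimator architectures.  Modules
# are environments carrying parameters, gradients and forward caches;
# nn_forward()/nn_backward() walk the module tree.  Convolutions call the
# compiled im2col/GEMM kernels; everything else is plain R linear algebra.

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$children <- list()
  class(m) <- "nn_module"
  m
}

# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) initialization for weights and biases
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

mod_dense <- function(nin, nout) {
  m <- new_module("dense")
  m$params$w <- init_uniform(c(nin, nout), nin)
  m$params$b <- as.vector(init_uniform(nout, nin))
  m
}

mod_relu <- function() new_module("relu")

mod_prelu <- function(init = 0.25) {
  m <- new_module("prelu")
  m$params$a <- init
  m
}

mod_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("bn")
  m$params$gamma <- rep(1, C)
  m$params$beta <- rep(0, C)
  m$buffers$run_mean <- rep(0, C)
  m$buffers$run_var <- rep(1, C)
  m$eps <- eps
  m$momentum <- momentum
  m
}

mod_conv <- function(cin, cout, k = 3L, stride = 1L, pad = NULL) {
  m <- new_module("conv")
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  m$params$w <- init_uniform(c(k, k, cin, cout), k * k * cin)
  m$params$b <- as.vector(init_uniform(cout, k * k * cin))
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m
}

mod_convt <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                      opad = NULL) {
  m <- new_module("convt")
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  if (is.null(opad)) opad <- stride - 1L
  m$params$w <- init_uniform(c(k, k, cout, cin), k * k * cin)
  m$params$b <- as.vector(init_uniform(cout, k * k * cin))
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$opad <- as.integer(opad)
  m
}

mod_seq <- function(children) {
  m <- new_module("seq")
  m$children <- children
  m
}

# Residual unit: `subunits` conv blocks (conv + BN + PReLU;
# the first carries the stride) plus a projection shortcut -- kernel-size
# conv when strided, 1x1 when only the channel count changes, identity
# otherwise.  `last_conv_only` drops normalization/activation after the
# final conv (used at the network output).
mod_resunit <- function(cin, cout, stride = 1L, subunits = 2L, k = 3L,
                        last_conv_only = FALSE) {
  path <- list()
  ci <- cin; s <- stride
  for (u in seq_len(subunits)) {
    path[[length(path) + 1L]] <- mod_conv(ci, cout, k, s)
    if (!(last_conv_only && u == subunits)) {
      path[[length(path) + 1L]] <- mod_bn(cout)
      path[[length(path) + 1L]] <- mod_prelu()
    }
    ci <- cout; s <- 1L
  }
  m <- new_module("resunit")
  m$children <- list(path = mod_seq(path))
  if (stride != 1L) {
    m$children$res <- mod_conv(cin, cout, k, stride)
  } else if (cin != cout) {
    m$children$res <- mod_conv(cin, cout, 1L, 1L, pad = 0L)
  }
  m
}

# skip connection: forward x through `sub` and concatenate (x, sub(x))
# along the channel dimension
mod_skip <- function(sub) {
  m <- new_module("skip")
  m$children <- list(sub = sub)
  m
}

# channel-dimension statistics helper: x is (H, W, C, N)
channel_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

nn_forward <- function(m, x, training = FALSE) {
  switch(m$type,
    dense = {
      m$cache <- list(x = x)
      sweep(x %*% m$params$w, 2L, m$params$b, "+")
    },
    relu = {
      m$cache <- list(pos = x > 0)
      x * (x > 0)
    },
    prelu = {
      m$cache <- list(x = x)
      a <- m$params$a
      pmax(x, 0) + a * pmin(x, 0)
    },
    bn = {
      d <- dim(x)
      C <- d[3]
      xm <- channel_matrix(x)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        nb <- nrow(xm)
        m$buffers$run_mean <- (1 - m$momentum) * m$buffers$run_mean + m$momentum * mu
        m$buffers$run_var <- (1 - m$momentum) * m$buffers$run_var +
          m$momentum * v * nb / max(nb - 1, 1)
      } else {
        mu <- m$buffers$run_mean
        v <- m$buffers$run_var
      }
      invstd <- 1 / sqrt(v + m$eps)
      xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, invstd, "*")
      ym <- sweep(sweep(xhat, 2L, m$params$gamma, "*"), 2L, m$params$beta, "+")
      m$cache <- list(xhat = xhat, invstd = invstd, d = d, training = training)
      aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    },
    conv = {
      m$cache <- list(x = x)
      nn_conv2d_fw(x, m$params$w, m$params$b, m$stride, m$pad)
    },
    convt = {
      m$cache <- list(x = x)
      nn_convt2d_fw(x, m$params$w, m$params$b, m$stride, m$pad, m$opad)
    },
    seq = {
      for (ch in m$children) x <- nn_forward(ch, x, training)
      x
    },
    resunit = {
      y <- nn_forward(m$children$path, x, training)
      r <- if (is.null(m$children$res)) x else nn_forward(m$children$res, x, training)
      y + r
    },
    skip = {
      y <- nn_forward(m$children$sub, x, training)
      m$cache <- list(cx = dim(x)[3])
      d <- dim(x)
      out <- array(0, c(d[1], d[2], d[3] + dim(y)[3], d[4]))
      out[, , seq_len(d[3]), ] <- x
      out[, , d[3] + seq_len(dim(y)[3]), ] <- y
      out
    },
    stop("unknown module type: ", m$type)
  )
}

nn_backward <- function(m, gy) {
  switch(m$type,
    dense = {
      x <- m$cache$x
      m$grads$w <- add_grad(m$grads$w, crossprod(x, gy))
      m$grads$b <- add_grad(m$grads$b, colSums(gy))
      gy %*% t(m$params$w)
    },
    relu = gy * m$cache$pos,
    prelu = {
      x <- m$cache$x
      m$grads$a <- add_grad(m$grads$a, sum(gy * pmin(x, 0)))
      gy * ifelse(x > 0, 1, m$params$a)
    },
    bn = {
      cc <- m$cache
      d <- cc$d
      gm <- channel_matrix(gy)
      m$grads$gamma <- add_grad(m$grads$gamma, colSums(gm * cc$xhat))
      m$grads$beta <- add_grad(m$grads$beta, colSums(gm))
      gxh <- sweep(gm, 2L, m$params$gamma, "*")
      if (cc$training) {
        mg <- colMeans(gxh)
        mgx <- colMeans(gxh * cc$xhat)
        gxm <- sweep(sweep(gxh, 2L, mg, "-") -
                       sweep(cc$xhat, 2L, mgx, "*"), 2L, cc$invstd, "*")
      } else {
        gxm <- sweep(gxh, 2L, cc$invstd, "*")
      }
      aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    conv = {
      g <- nn_conv2d_bw(m$cache$x, m$params$w, gy, m$stride, m$pad)
      m$grads$w <- add_grad(m$grads$w, g$gw)
      m$grads$b <- add_grad(m$grads$b, g$gb)
      g$gx
    },
    convt = {
      g <- nn_convt2d_bw(m$cache$x, m$params$w, gy, m$stride, m$pad)
      m$grads$w <- add_grad(m$grads$w, g$gw)
      m$grads$b <- add_grad(m$grads$b, g$gb)
      g$gx
    },
    seq = {
      for (ch in rev(m$children)) gy <- nn_backward(ch, gy)
      gy
    },
    resunit = {
      gx <- nn_backward(m$children$path, gy)
      gr <- if (is.null(m$children$res)) gy else nn_backward(m$children$res, gy)
      gx + gr
    },
    skip = {
      cx <- m$cache$cx
      ctot <- dim(gy)[3]
      gx <- gy[, , seq_len(cx), , drop = FALSE]
      gsub <- gy[, , (cx + 1L):ctot, , drop = FALSE]
      gx + nn_backward(m$children$sub, gsub)
    },
    stop("unknown module type: ", m$type)
  )
}

add_grad <- function(old, g) if (is.null(old)) g else old + g

zero_grads <- function(m) {
  m$grads <- list()
  for (ch in m$children) zero_grads(ch)
  invisible(NULL)
}

# Flat list of (module, name) parameter references in a stable walk order
param_refs <- function(m, acc = list()) {
  for (nm in names(m$params))
    acc[[length(acc) + 1L]] <- list(mod = m, name = nm)
  for (ch in m$children) acc <- param_refs(ch, acc)
  acc
}

get_param_state <- function(m) {
  lapply(param_refs(m), function(ref) ref$mod$params[[ref$name]])
}

buffer_refs <- function(m, acc = list()) {
  for (nm in names(m$buffers))
    acc[[length(acc) + 1L]] <- list(mod = m, name = nm)
  for (ch in m$children) acc <- buffer_refs(ch, acc)
  acc
}

# Complete snapshot (weights + normalization running statistics)
get_model_state <- function(m) {
  list(params = get_param_state(m),
       buffers = lapply(buffer_refs(m), function(ref) ref$mod$buffers[[ref$name]]))
}

set_model_state <- function(m, state) {
  set_param_state(m, state$params)
  refs <- buffer_refs(m)
  stopifnot(length(refs) == length(state$buffers))
  for (i in seq_along(refs))
    refs[[i]]$mod$buffers[[refs[[i]]$name]] <- state$buffers[[i]]
  invisible(NULL)
}

set_param_state <- function(m, state) {
  refs <- param_refs(m)
  stopifnot(length(refs) == length(state))
  for (i in seq_along(refs))
    refs[[i]]$mod$params[[refs[[i]]$name]] <- state[[i]]
  invisible(NULL)
}

# Decoupled-weight-decay Adam (AdamW).  Decay is not applied to
# normalization parameters or biases, following common practice.
adamw_new <- function(refs, lr = 2e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$refs <- refs
  st$m <- lapply(refs, function(ref) ref$mod$params[[ref$name]] * 0)
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$wd <- weight_decay
  st$decay <- vapply(refs, function(ref) ref$name == "w", logical(1))
  st
}

adamw_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$refs)) {
    ref <- st$refs[[i]]
    g <- ref$mod$grads[[ref$name]]
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    p <- ref$mod$params[[ref$name]]
    if (st$decay[i]) p <- p * (1 - st$lr * st$wd)
    ref$mod$params[[ref$name]] <-
      p - st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}

clear_caches <- function(m) {
  m$cache <- NULL
  for (ch in m$children) clear_caches(ch)
  invisible(NULL)
}
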