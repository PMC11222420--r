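# Minimal dense-layer framework backing the modified U-Net. Each module is
# an environment holding parameters, their gradients, and the forward cache;
# every module instance appears exactly once in the network graph, so caches
# are overwritten per step. Tensors are (H, W, C, N) double arrays.

new_module <- function(type, params = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- list()
  e$state <- list()
  e$sub <- list()
  class(e) <- "uroseg_module"
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L) {
  m <- new_module("conv", list(W = he_init(cin * k * k, cout, cin * k * k),
                               b = numeric(cout)))
  m$k <- as.integer(k); m$pad <- as.integer(pad)
  m$cin <- cin; m$cout <- cout
  m
}

nn_convT <- function(cin, cout) {
  m <- new_module("convT", list(W = he_init(cin, cout * 4L, cin),
                                b = numeric(cout)))
  m$cin <- cin; m$cout <- cout
  m
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  m <- new_module("bn", list(gamma = rep(1, c), beta = rep(0, c)))
  m$state$running_mean <- rep(0, c)
  m$state$running_var <- rep(1, c)
  m$momentum <- momentum; m$eps <- eps; m$c <- c
  m
}

nn_relu <- function() new_module("relu")
nn_sigmoid <- function() new_module("sigmoid")
nn_maxpool <- function() new_module("maxpool")
nn_identity <- function() new_module("identity")

nn_seq <- function(...) {
  m <- new_module("seq")
  m$sub <- list(...)
  m
}

# Residual block: conv3-norm-relu-conv3-norm (+ projection shortcut on
# channel change), then relu.
nn_resblock <- function(cin, cout, norm = "batch") {
  mknorm <- function(c) if (norm == "batch") nn_bn(c) else nn_identity()
  m <- new_module("resblock")
  m$sub <- list(conv1 = nn_conv(cin, cout, 3L), n1 = mknorm(cout),
                r1 = nn_relu(),
                conv2 = nn_conv(cout, cout, 3L), n2 = mknorm(cout),
                rout = nn_relu())
  if (cin != cout) {
    m$sub$short_conv <- nn_conv(cin, cout, 1L, 0L)
    m$sub$short_norm <- mknorm(cout)
  }
  m
}

bn_reshape <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
bn_unshape <- function(m, d) {
  aperm(array(m, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$type,
    identity = x,
    conv = {
      mod$cache <- list(x = x)
      conv2d_fwd(x, mod$params$W, mod$params$b, mod$k, mod$pad)
    },
    convT = {
      mod$cache <- list(x = x)
      convT2_fwd(x, mod$params$W, mod$params$b)
    },
    bn = {
      d <- dim(x)
      xm <- bn_reshape(x)
      if (training) {
        mu <- colMeans(xm)
        va <- colMeans(xm * xm) - mu^2
        va[va < 0] <- 0
        mod$state$running_mean <- (1 - mod$momentum) * mod$state$running_mean +
          mod$momentum * mu
        mod$state$running_var <- (1 - mod$momentum) * mod$state$running_var +
          mod$momentum * va
      } else {
        mu <- mod$state$running_mean
        va <- mod$state$running_var
      }
      invstd <- 1 / sqrt(va + mod$eps)
      xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
      ym <- sweep(sweep(xhat, 2, mod$params$gamma, "*"), 2, mod$params$beta, "+")
      mod$cache <- list(xhat = xhat, invstd = invstd, d = d,
                        training = training)
      bn_unshape(ym, d)
    },
    relu = {
      mod$cache <- list(mask = x > 0)
      x * (x > 0)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      mod$cache <- list(y = y)
      y
    },
    maxpool = {
      r <- maxpool2_fwd(x)
      mod$cache <- list(idx = r$idx, H = dim(x)[1], W = dim(x)[2])
      r$y
    },
    seq = {
      for (s in mod$sub) x <- nn_forward(s, x, training)
      x
    },
    resblock = {
      s <- mod$sub
      mod$cache <- list(x = x)
      h <- nn_forward(s$conv1, x, training)
      h <- nn_forward(s$n1, h, training)
      h <- nn_forward(s$r1, h, training)
      h <- nn_forward(s$conv2, h, training)
      h <- nn_forward(s$n2, h, training)
      sc <- if (is.null(s$short_conv)) x else {
        nn_forward(s$short_norm, nn_forward(s$short_conv, x, training), training)
      }
      nn_forward(s$rout, h + sc)
    },
    stop(sprintf("unknown module type '%s'", mod$type))
  )
}

nn_backward <- function(mod, dy) {
  switch(mod$type,
    identity = dy,
    conv = {
      r <- conv2d_bwd(mod$cache$x, mod$params$W, dy, mod$k, mod$pad)
      mod$grads <- list(W = r$dw, b = r$db)
      r$dx
    },
    convT = {
      r <- convT2_bwd(mod$cache$x, mod$params$W, dy)
      mod$grads <- list(W = r$dw, b = r$db)
      r$dx
    },
    bn = {
      cc <- mod$cache
      dym <- bn_reshape(dy)
      dgamma <- colSums(dym * cc$xhat)
      dbeta <- colSums(dym)
      mod$grads <- list(gamma = dgamma, beta = dbeta)
      if (cc$training) {
        dxhat <- sweep(dym, 2, mod$params$gamma, "*")
        n <- nrow(dxhat)
        t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
        t2 <- sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), "*")
        dxm <- sweep(t1 - t2, 2, cc$invstd, "*")
      } else {
        dxm <- sweep(sweep(dym, 2, mod$params$gamma, "*"), 2, cc$invstd, "*")
      }
      bn_unshape(dxm, cc$d)
    },
    relu = dy * mod$cache$mask,
    sigmoid = dy * mod$cache$y * (1 - mod$cache$y),
    maxpool = maxpool2_bwd(dy, mod$cache$idx, mod$cache$H, mod$cache$W),
    seq = {
      for (s in rev(mod$sub)) dy <- nn_backward(s, dy)
      dy
    },
    resblock = {
      s <- mod$sub
      dsum <- nn_backward(s$rout, dy)
      dh <- nn_backward(s$n2, dsum)
      dh <- nn_backward(s$conv2, dh)
      dh <- nn_backward(s$r1, dh)
      dh <- nn_backward(s$n1, dh)
      dx <- nn_backward(s$conv1, dh)
      if (is.null(s$short_conv)) {
        dx + dsum
      } else {
        dsc <- nn_backward(s$short_norm, dsum)
        dx + nn_backward(s$short_conv, dsc)
      }
    },
    stop(sprintf("unknown module type '%s'", mod$type))
  )
}

# All parameter-bearing module environments below `mod` (depth-first).
collect_param_modules <- function(mod) {
  out <- list()
  if (length(mod$params) > 0) out <- list(mod)
  for (s in mod$sub) out <- c(out, collect_param_modules(s))
  out
}

n_params_module <- function(mod) {
  sum(vapply(collect_param_modules(mod),
             function(m) sum(vapply(m$params, length, numeric(1))),
             numeric(1)))
}

# ---- Adam ----

adam_state <- function(modules, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$modules <- modules
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  for (m in modules) {
    m$adam <- lapply(m$params, function(p) list(m = p * 0, v = p * 0))
  }
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (m in st$modules) {
    for (nm in names(m$params)) {
      g <- m$grads[[nm]]
      if (is.null(g)) next
      a <- m$adam[[nm]]
      a$m <- st$beta1 * a$m + (1 - st$beta1) * g
      a$v <- st$beta2 * a$v + (1 - st$beta2) * g * g
      m$adam[[nm]] <- a
      m$params[[nm]] <- m$params[[nm]] -
        st$lr * (a$m / bc1) / (sqrt(a$v / bc2) + st$eps)
    }
  }
  invisible(st)
}

# ---- bilinear resize (used to upscale deep-supervision side outputs) ----

interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5  # 0-based source position
    i0 <- floor(s)
    w <- s - i0
    lo <- min(max(i0 + 1, 1), n_in)
    hi <- min(lo + 1, n_in)
    if (lo == hi) w <- 0
    A[i, lo] <- A[i, lo] + (1 - w)
    A[i, hi] <- A[i, hi] + w
  }
  A
}

apply_axis1 <- function(x, A) {
  d <- dim(x)
  y <- A %*% matrix(x, nrow = d[1])
  array(y, dim = c(nrow(A), d[-1]))
}

apply_axis2 <- function(x, A) {
  d <- dim(x)
  perm <- c(2, 1, seq_along(d)[-(1:2)])
  xp <- aperm(x, perm)
  y <- A %*% matrix(xp, nrow = d[2])
  dp <- c(nrow(A), d[1], d[-(1:2)])
  aperm(array(y, dim = dp), order(perm))
}

#' Bilinear resize of a (H, W, ...) array
#' @param x array whose first two axes are spatial.
#' @param out_h,out_w target spatial size.
#' @return resized array.
#' @keywords internal
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  if (d[1] != out_h) x <- apply_axis1(x, interp_matrix(d[1], out_h))
  if (d[2] != out_w) x <- apply_axis2(x, interp_matrix(d[2], out_w))
  x
}

# transpose (adjoint) of resize_bilinear: maps a gradient on the resized
# grid back to the source grid
resize_bilinear_bwd <- function(g, in_h, in_w) {
  d <- dim(g)
  if (d[1] != in_h) g <- apply_axis1(g, t(interp_matrix(in_h, d[1])))
  if (d[2] != in_w) g <- apply_axis2(g, t(interp_matrix(in_w, d[2])))
  g
}
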