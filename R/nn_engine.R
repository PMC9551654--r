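# Minimal CNN engine: layers as mutable environments, tensors as numeric
# arrays with dim (H, W, C, N). Convolution runs through im2col (patch
# matrix x weight matrix products on BLAS); backward scatters gradients
# with rowsum(). Everything is plain R so training stays fully seeded and
# deterministic.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("lp_layer_", type), "lp_layer")
  e
}

# He-normal initialization; relies on the caller having seeded the RNG.
init_weights <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / max(1, fan_in)))
}

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                       depthwise = FALSE, bias = TRUE) {
  kk <- k * k
  if (depthwise) {
    stopifnot(out_ch == in_ch)
    W <- matrix(init_weights(kk * in_ch, kk), kk, in_ch)
  } else {
    W <- matrix(init_weights(kk * in_ch * out_ch, kk * in_ch), kk * in_ch, out_ch)
  }
  new_layer("conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            depthwise = depthwise, W = W,
            b = if (bias) numeric(out_ch) else NULL,
            idx_cache = list())
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", ch = ch, momentum = momentum, eps = eps,
            gamma = rep(1, ch), beta = numeric(ch),
            run_mean = numeric(ch), run_var = rep(1, ch))
}

layer_act <- function(kind = c("relu", "relu6")) {
  new_layer("act", kind = match.arg(kind))
}

layer_maxpool <- function(k, stride = k, pad = 0L) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), idx_cache = list())
}

layer_adaptive_avgpool <- function(out_size = 1L) {
  new_layer("avgpool", out_size = as.integer(out_size))
}

layer_flatten <- function() new_layer("flatten")

layer_dense <- function(in_f, out_f) {
  new_layer("dense", in_f = in_f, out_f = out_f,
            W = matrix(init_weights(in_f * out_f, in_f), out_f, in_f),
            b = numeric(out_f))
}

layer_dropout <- function(p) new_layer("dropout", p = p)

# Residual block: sequential sublayers with optional identity skip.
layer_block <- function(layers, residual = FALSE) {
  new_layer("block", layers = layers, residual = residual)
}

# -- im2col index construction (cached per input shape) ----------------------

conv_indices <- function(env, H, W, C, N, k, stride, pad) {
  key <- paste(H, W, C, N, k, stride, pad, sep = "x")
  hit <- env$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oH <- (Hp - k) %/% stride + 1L
  oW <- (Wp - k) %/% stride + 1L
  kk <- k * k
  off <- rep(0:(k - 1L), times = k) + rep(0:(k - 1L), each = k) * Hp
  r0 <- (0:(oH - 1L)) * stride + 1L
  c0 <- (0:(oW - 1L)) * stride + 1L
  base <- rep(r0, times = oW) + (rep(c0, each = oH) - 1L) * Hp
  I <- outer(off, base, "+")                              # kk x oHoW
  I <- I[rep(seq_len(kk), times = C), , drop = FALSE] +
    rep(0:(C - 1L), each = kk) * (Hp * Wp)                # kk*C x oHoW
  len <- length(I)
  idx <- rep(as.vector(I), N) +
    rep((0:(N - 1L)) * (Hp * Wp * C), each = len)
  dim(idx) <- c(kk * C, oH * oW * N)
  out <- list(idx = idx, Hp = Hp, Wp = Wp, oH = oH, oW = oW)
  env$idx_cache[[key]] <- out
  out
}

pad_input <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

unpad_grad <- function(g, pad, H, W) {
  if (pad == 0L) return(g)
  g[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
}

scatter_add <- function(values, index, length_out) {
  rs <- rowsum(as.vector(values), group = as.vector(index))
  out <- numeric(length_out)
  out[as.integer(rownames(rs))] <- rs
  out
}

# -- forward / backward ------------------------------------------------------

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = conv_forward(layer, x, training),
    bn = bn_forward(layer, x, training),
    act = act_forward(layer, x, training),
    maxpool = maxpool_forward(layer, x, training),
    avgpool = avgpool_forward(layer, x, training),
    flatten = { layer$in_dim <- dim(x); matrix(x, prod(dim(x)[1:3]), dim(x)[4]) },
    dense = { layer$x <- x; layer$W %*% x + layer$b },
    dropout = dropout_forward(layer, x, training),
    block = block_forward(layer, x, training),
    rlang::abort(paste0("unknown layer type ", layer$type))
  )
}

nn_backward <- function(layer, dy) {
  switch(layer$type,
    conv = conv_backward(layer, dy),
    bn = bn_backward(layer, dy),
    act = act_backward(layer, dy),
    maxpool = maxpool_backward(layer, dy),
    avgpool = avgpool_backward(layer, dy),
    flatten = array(dy, layer$in_dim),
    dense = {
      layer$gW <- dy %*% t(layer$x)
      layer$gb <- rowSums(dy)
      t(layer$W) %*% dy
    },
    dropout = if (is.null(layer$mask)) dy else dy * layer$mask,
    block = block_backward(layer, dy),
    rlang::abort(paste0("unknown layer type ", layer$type))
  )
}

conv_forward <- function(layer, x, training) {
  d <- dim(x)
  ci <- conv_indices(layer, d[1], d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  xp <- pad_input(x, layer$pad)
  Xcol <- matrix(xp[as.vector(ci$idx)], nrow(ci$idx), ncol(ci$idx))
  M <- ci$oH * ci$oW * d[4]
  if (layer$depthwise) {
    kk <- layer$k^2; C <- layer$in_ch
    prod <- Xcol * as.vector(layer$W)      # recycles (kk*C) down each column
    Y <- colSums(array(prod, c(kk, C * M)))    # sum over kk
    Ymat <- matrix(Y, C, M)                    # C x (oHoW*N)
  } else {
    Ymat <- crossprod(layer$W, Xcol)           # Cout x (oHoW*N)
  }
  if (!is.null(layer$b)) Ymat <- Ymat + layer$b
  if (training) { layer$Xcol <- Xcol; layer$ci <- ci; layer$in_dim <- d }
  aperm(array(Ymat, c(layer$out_ch, ci$oH, ci$oW, d[4])), c(2, 3, 1, 4))
}

conv_backward <- function(layer, dy) {
  d <- layer$in_dim; ci <- layer$ci
  M <- ci$oH * ci$oW * d[4]
  dYmat <- matrix(aperm(dy, c(3, 1, 2, 4)), layer$out_ch, M)
  if (!is.null(layer$b)) layer$gb <- rowSums(dYmat)
  if (layer$depthwise) {
    kk <- layer$k^2; C <- layer$in_ch
    dYexp <- dYmat[rep(seq_len(C), each = kk), , drop = FALSE]
    layer$gW <- matrix(rowSums(layer$Xcol * dYexp), kk, C)
    dXcol <- dYexp * as.vector(layer$W)
  } else {
    layer$gW <- layer$Xcol %*% t(dYmat)
    dXcol <- layer$W %*% dYmat
  }
  len <- (d[1] + 2L * layer$pad) * (d[2] + 2L * layer$pad) * d[3] * d[4]
  dxp <- array(scatter_add(dXcol, ci$idx, len),
               c(d[1] + 2L * layer$pad, d[2] + 2L * layer$pad, d[3], d[4]))
  layer$Xcol <- NULL
  unpad_grad(dxp, layer$pad, d[1], d[2])
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])  # (H*W*N) x C
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean; v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xm, 2, mu) * rep(inv, each = nrow(xm))
  y <- sweep(xhat * rep(layer$gamma, each = nrow(xm)), 2, layer$beta, "+")
  if (training) { layer$xhat <- xhat; layer$inv <- inv; layer$in_dim <- d }
  aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_backward <- function(layer, dy) {
  d <- layer$in_dim
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
  m <- nrow(dym)
  layer$ggamma <- colSums(dym * layer$xhat)
  layer$gbeta <- colSums(dym)
  # dL/dxhat = dy * gamma; standard batch-norm backward
  dxhat <- dym * rep(layer$gamma, each = m)
  dx <- (dxhat - rep(colMeans(dxhat), each = m) -
           layer$xhat * rep(colMeans(dxhat * layer$xhat), each = m)) *
    rep(layer$inv, each = m)
  layer$xhat <- NULL
  aperm(array(dx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

act_forward <- function(layer, x, training) {
  y <- if (layer$kind == "relu") pmax(x, 0) else pmin(pmax(x, 0), 6)
  if (training) layer$mask <- (x > 0) & (if (layer$kind == "relu6") x < 6 else TRUE)
  y
}

act_backward <- function(layer, dy) dy * layer$mask

maxpool_forward <- function(layer, x, training) {
  d <- dim(x)
  ci <- conv_indices(layer, d[1], d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  xp <- pad_input(x, layer$pad, value = -Inf)
  kk <- layer$k^2; C <- d[3]; M <- ci$oH * ci$oW * d[4]
  Xcol <- matrix(xp[as.vector(ci$idx)], kk * C, M)
  arr <- matrix(Xcol, kk, C * M)
  cur <- arr[1, ]; am <- rep(1L, C * M)
  for (j in seq_len(kk)[-1]) {
    upd <- arr[j, ] > cur
    am[upd] <- j; cur[upd] <- arr[j, upd]
  }
  if (training) {
    layer$am <- am; layer$ci <- ci; layer$in_dim <- d
  }
  # arr column q = (c, m) with c fastest; output wants (C, oHoW*N)
  aperm(array(cur, c(C, ci$oH, ci$oW, d[4])), c(2, 3, 1, 4))
}

maxpool_backward <- function(layer, dy) {
  d <- layer$in_dim; ci <- layer$ci
  kk <- layer$k^2; C <- d[3]; M <- ci$oH * ci$oW * d[4]
  dYvec <- as.vector(matrix(aperm(dy, c(3, 1, 2, 4)), C, M))  # (c fastest, m)
  cvec <- rep(seq_len(C), times = M)
  mvec <- rep(seq_len(M), each = C)
  rows <- layer$am + (cvec - 1L) * kk
  target <- ci$idx[cbind(rows, mvec)]
  Hp <- d[1] + 2L * layer$pad; Wp <- d[2] + 2L * layer$pad
  dxp <- array(scatter_add(dYvec, target, Hp * Wp * C * d[4]),
               c(Hp, Wp, C, d[4]))
  unpad_grad(dxp, layer$pad, d[1], d[2])
}

avgpool_forward <- function(layer, x, training) {
  d <- dim(x); S <- layer$out_size
  if (training) layer$in_dim <- d
  if (S == 1L) {
    y <- apply(x, c(3, 4), mean)
    return(array(y, c(1, 1, d[3], d[4])))
  }
  lo_h <- floor((0:(S - 1)) * d[1] / S) + 1L; hi_h <- ceiling((1:S) * d[1] / S)
  lo_w <- floor((0:(S - 1)) * d[2] / S) + 1L; hi_w <- ceiling((1:S) * d[2] / S)
  y <- array(0, c(S, S, d[3], d[4]))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    y[i, j, , ] <- apply(x[lo_h[i]:hi_h[i], lo_w[j]:hi_w[j], , , drop = FALSE],
                         c(3, 4), mean)
  }
  layer$bins <- list(lo_h = lo_h, hi_h = hi_h, lo_w = lo_w, hi_w = hi_w)
  y
}

avgpool_backward <- function(layer, dy) {
  d <- layer$in_dim; S <- layer$out_size
  dx <- array(0, d)
  if (S == 1L) {
    per <- 1 / (d[1] * d[2])
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      dx[, , c, n] <- dy[1, 1, c, n] * per
    }
    return(dx)
  }
  b <- layer$bins
  for (i in seq_len(S)) for (j in seq_len(S)) {
    hh <- b$lo_h[i]:b$hi_h[i]; ww <- b$lo_w[j]:b$hi_w[j]
    per <- 1 / (length(hh) * length(ww))
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      dx[hh, ww, c, n] <- dx[hh, ww, c, n] + dy[i, j, c, n] * per
    }
  }
  dx
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$p <= 0) { layer$mask <- NULL; return(x) }
  layer$mask <- (array(stats::runif(length(x)), dim(x)) >= layer$p) / (1 - layer$p)
  x * layer$mask
}

block_forward <- function(layer, x, training) {
  y <- x
  for (l in layer$layers) y <- nn_forward(l, y, training)
  if (layer$residual) y <- y + x
  y
}

block_backward <- function(layer, dy) {
  dx <- dy
  for (l in rev(layer$layers)) dx <- nn_backward(l, dx)
  if (layer$residual) dx <- dx + dy
  dx
}

# -- parameter plumbing ------------------------------------------------------

walk_layers <- function(layers, fn) {
  for (l in layers) {
    if (l$type == "block") walk_layers(l$layers, fn) else fn(l)
  }
  invisible(NULL)
}

layer_param_names <- function(layer) {
  switch(layer$type,
    conv = c("W", if (!is.null(layer$b)) "b"),
    bn = c("gamma", "beta"),
    dense = c("W", "b"),
    character()
  )
}

layer_grad_name <- function(p) {
  c(W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta")[[p]]
}

model_parameters <- function(model) {
  out <- list()
  i <- 0
  walk_layers(model$layers, function(l) {
    for (p in layer_param_names(l)) {
      i <<- i + 1
      out[[i]] <<- list(layer = l, name = p)
    }
  })
  out
}

#' Count trainable parameters of a model
#'
#' Sums the lengths of every trainable array: convolution and dense weights
#' and biases, batch-norm scales and shifts (running statistics are buffers,
#' not parameters).
#'
#' @param model A model from [build_model()].
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "lp_model"))
  total <- 0
  walk_layers(model$layers, function(l) {
    for (p in layer_param_names(l)) total <<- total + length(get(p, envir = l))
  })
  total
}

# Snapshot / restore weights (used to keep the best-validation model).
model_state <- function(model) {
  st <- list(); i <- 0
  walk_layers(model$layers, function(l) {
    nms <- c(layer_param_names(l), if (l$type == "bn") c("run_mean", "run_var"))
    for (p in nms) { i <<- i + 1; st[[i]] <<- get(p, envir = l) }
  })
  st
}

model_restore <- function(model, state) {
  i <- 0
  walk_layers(model$layers, function(l) {
    nms <- c(layer_param_names(l), if (l$type == "bn") c("run_mean", "run_var"))
    for (p in nms) { i <<- i + 1; assign(p, state[[i]], envir = l) }
  })
  invisible(model)
}

adam_init <- function(model) {
  walk_layers(model$layers, function(l) {
    for (p in layer_param_names(l)) {
      assign(paste0(".m_", p), get(p, envir = l) * 0, envir = l)
      assign(paste0(".v_", p), get(p, envir = l) * 0, envir = l)
    }
  })
  model$adam_t <- 0L
  invisible(model)
}

adam_step <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  model$adam_t <- model$adam_t + 1L
  t <- model$adam_t
  walk_layers(model$layers, function(l) {
    for (p in layer_param_names(l)) {
      g <- get(layer_grad_name(p), envir = l)
      m <- beta1 * get(paste0(".m_", p), envir = l) + (1 - beta1) * g
      v <- beta2 * get(paste0(".v_", p), envir = l) + (1 - beta2) * g^2
      assign(paste0(".m_", p), m, envir = l)
      assign(paste0(".v_", p), v, envir = l)
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mh / (sqrt(vh) + eps), envir = l)
    }
  })
  invisible(model)
}

model_forward <- function(model, x, training = FALSE) {
  for (l in model$layers) x <- nn_forward(l, x, training)
  x
}

model_backward <- function(model, dy) {
  for (l in rev(model$layers)) dy <- nn_backward(l, dy)
  dy
}
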