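# Minimal batched neural-network engine: conv/depthwise/separable stacks with
# hand-written backprop and DeepLIFT rescale-rule multiplier backpropagation.
# Activations are arrays (C, H, W, N) for spatial layers and matrices
# (features, N) after flattening; convolution is im2col + BLAS matmul.

nn_layer <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = c(paste0("nn_", type), "nn_layer"))
}

#' Convolutional layer (stride 1, optional zero padding)
#'
#' @param out_ch number of output channels (kernels)
#' @param kh,kw kernel height/width
#' @param pad length-2 integer vector of zero padding (rows, cols)
#' @param mask optional 0/1 weight mask (for grouped/depthwise convolutions);
#'   masked-out weights are frozen at zero and excluded from parameter counts
#' @keywords internal
nn_conv2d <- function(out_ch, kh, kw, pad = c(0L, 0L), mask = NULL) {
  nn_layer("conv2d", out_ch = out_ch, kh = kh, kw = kw, pad = as.integer(pad),
           mask = mask)
}

# Depthwise convolution: each input channel gets `mult` private kernels of
# shape kh x kw. Implemented as a masked full convolution; the block-diagonal
# mask zeroes cross-channel weights.
nn_depthwise <- function(mult, kh, kw, pad = c(0L, 0L)) {
  nn_layer("depthwise", mult = mult, kh = kh, kw = kw, pad = as.integer(pad))
}

nn_maxpool  <- function(ph, pw) nn_layer("maxpool", ph = as.integer(ph), pw = as.integer(pw))
nn_avgpool  <- function(ph, pw) nn_layer("avgpool", ph = as.integer(ph), pw = as.integer(pw))
nn_batchnorm <- function() nn_layer("batchnorm")
nn_relu     <- function() nn_layer("relu")
nn_dropout  <- function(p = 0.5) nn_layer("dropout", p = p)
nn_flatten  <- function() nn_layer("flatten")
nn_dense    <- function(out_dim) nn_layer("dense", out_dim = as.integer(out_dim))

# ---- shape inference / parameter initialisation -----------------------------

conv_geometry <- function(layer, in_shape) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  ph <- layer$pad[1]; pw <- layer$pad[2]
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  oH <- Hp - layer$kh + 1L; oW <- Wp - layer$kw + 1L
  if (oH < 1L || oW < 1L)
    stop("conv kernel ", layer$kh, "x", layer$kw, " larger than padded input ",
         Hp, "x", Wp)
  # linear-index map into the padded (C, Hp, Wp) volume: K x P
  c_i <- seq_len(C)
  off <- as.vector(outer(outer(c_i, (seq_len(layer$kh) - 1L) * C, "+"),
                         (seq_len(layer$kw) - 1L) * C * Hp, "+"))
  base <- as.vector(outer((seq_len(oH) - 1L) * C, (seq_len(oW) - 1L) * C * Hp, "+"))
  idx <- outer(off, base, "+")
  list(C = C, H = H, W = W, Hp = Hp, Wp = Wp, oH = oH, oW = oW,
       K = C * layer$kh * layer$kw, P = oH * oW,
       idx0 = as.integer(as.vector(idx) - 1L))
}

ly_build <- function(layer, in_shape) UseMethod("ly_build")

ly_build.nn_conv2d <- function(layer, in_shape) {
  stopifnot(length(in_shape) == 3)
  g <- conv_geometry(layer, in_shape)
  layer$geom <- g
  layer$in_shape <- in_shape
  layer$out_shape <- c(layer$out_ch, g$oH, g$oW)
  fan_in <- if (is.null(layer$mask)) g$K else max(rowSums(layer$mask))
  lim <- sqrt(6 / fan_in)
  W <- matrix(stats::runif(layer$out_ch * g$K, -lim, lim), layer$out_ch, g$K)
  if (!is.null(layer$mask)) W <- W * layer$mask
  layer$par <- list(W = W, b = numeric(layer$out_ch))
  layer
}

ly_build.nn_depthwise <- function(layer, in_shape) {
  C <- in_shape[1]
  out_ch <- C * layer$mult
  # mask: output channel o = (c-1)*mult + m reads only input channel c
  kk <- layer$kh * layer$kw
  mask <- matrix(0, out_ch, C * kk)
  for (c in seq_len(C)) {
    cols <- c + (seq_len(kk) - 1L) * C          # entries of channel c in im2col order
    rows <- (c - 1L) * layer$mult + seq_len(layer$mult)
    mask[rows, cols] <- 1
  }
  conv <- nn_conv2d(out_ch, layer$kh, layer$kw, layer$pad, mask = mask)
  ly_build(conv, in_shape)
}

ly_build.nn_avgpool <- ly_build.nn_maxpool <- function(layer, in_shape) {
  stopifnot(length(in_shape) == 3)
  layer$in_shape <- in_shape
  layer$out_shape <- c(in_shape[1], in_shape[2] %/% layer$ph, in_shape[3] %/% layer$pw)
  layer
}

ly_build.nn_batchnorm <- function(layer, in_shape) {
  C <- in_shape[1]
  layer$in_shape <- layer$out_shape <- in_shape
  layer$par <- list(gamma = rep(1, C), beta = numeric(C))
  layer$run_mean <- numeric(C)
  layer$run_var <- rep(1, C)
  layer$momentum <- 0.9
  layer$eps <- 1e-5
  layer
}

ly_build.nn_relu <- function(layer, in_shape) {
  layer$in_shape <- layer$out_shape <- in_shape; layer
}

ly_build.nn_dropout <- function(layer, in_shape) {
  layer$in_shape <- layer$out_shape <- in_shape; layer
}

ly_build.nn_flatten <- function(layer, in_shape) {
  layer$in_shape <- in_shape
  layer$out_shape <- prod(in_shape)
  layer
}

ly_build.nn_dense <- function(layer, in_shape) {
  stopifnot(length(in_shape) == 1)
  layer$in_shape <- in_shape
  layer$out_shape <- layer$out_dim
  lim <- sqrt(6 / in_shape)
  layer$par <- list(W = matrix(stats::runif(layer$out_dim * in_shape, -lim, lim),
                               layer$out_dim, in_shape),
                    b = numeric(layer$out_dim))
  layer
}

# ---- forward ---------------------------------------------------------------

ly_forward <- function(layer, x, training = FALSE) UseMethod("ly_forward")

pad_input <- function(x, g) {
  if (g$Hp == g$H && g$Wp == g$W) return(x)
  N <- dim(x)[4]
  xp <- array(0, c(g$C, g$Hp, g$Wp, N))
  ph <- (g$Hp - g$H) %/% 2L; pw <- (g$Wp - g$W) %/% 2L
  xp[, ph + seq_len(g$H), pw + seq_len(g$W), ] <- x
  xp
}

ly_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  g <- layer$geom
  N <- dim(x)[4]
  xp <- pad_input(x, g)
  dim(xp) <- c(g$C * g$Hp * g$Wp, N)
  Xc <- gather_cols_cpp(xp, g$idx0, g$K, g$P)
  out <- layer$par$W %*% Xc + layer$par$b
  dim(out) <- c(layer$out_ch, g$oH, g$oW, N)
  list(out = out, cache = list(Xc = Xc, N = N), layer = layer)
}

ly_forward.nn_maxpool <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  oH <- H %/% layer$ph; oW <- W %/% layer$pw
  mx <- array(-Inf, c(C, oH, oW, N))
  arg <- array(0L, c(C, oH, oW, N))
  o <- 0L
  for (dw in seq_len(layer$pw)) for (dh in seq_len(layer$ph)) {
    o <- o + 1L
    sub <- x[, seq(dh, by = layer$ph, length.out = oH),
             seq(dw, by = layer$pw, length.out = oW), , drop = FALSE]
    upd <- sub > mx
    mx[upd] <- sub[upd]
    arg[upd] <- o
  }
  list(out = mx, cache = list(arg = arg, dims = d, out = mx, x_in = x),
       layer = layer)
}

ly_forward.nn_avgpool <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[1]
  oH <- d[2] %/% layer$ph; oW <- d[3] %/% layer$pw
  acc <- array(0, c(C, oH, oW, d[4]))
  for (dw in seq_len(layer$pw)) for (dh in seq_len(layer$ph)) {
    acc <- acc + x[, seq(dh, by = layer$ph, length.out = oH),
                   seq(dw, by = layer$pw, length.out = oW), , drop = FALSE]
  }
  list(out = acc / (layer$ph * layer$pw), cache = list(dims = d), layer = layer)
}

ly_forward.nn_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, length(x) %/% C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var  <- layer$momentum * layer$run_var  + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  ivar <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * ivar
  out <- layer$par$gamma * xhat + layer$par$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, ivar = ivar, dims = d, training = training),
       layer = layer)
}

ly_forward.nn_relu <- function(layer, x, training = FALSE) {
  list(out = x * (x > 0), cache = list(x = x), layer = layer)
}

ly_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if (!training) return(list(out = x, cache = list(mask = NULL), layer = layer))
  mask <- array((stats::runif(length(x)) > layer$p) / (1 - layer$p), dim(x))
  list(out = x * mask, cache = list(mask = mask), layer = layer)
}

ly_forward.nn_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  list(out = x, cache = list(dims = d), layer = layer)
}

ly_forward.nn_dense <- function(layer, x, training = FALSE) {
  list(out = layer$par$W %*% x + layer$par$b, cache = list(x = x), layer = layer)
}

# ---- backward --------------------------------------------------------------

ly_backward <- function(layer, dout, cache) UseMethod("ly_backward")

ly_backward.nn_conv2d <- function(layer, dout, cache) {
  g <- layer$geom
  N <- cache$N
  dim(dout) <- c(layer$out_ch, g$P * N)
  dW <- tcrossprod(dout, cache$Xc)
  if (!is.null(layer$mask)) dW <- dW * layer$mask
  db <- rowSums(dout)
  dXc <- crossprod(layer$par$W, dout)
  dxp <- scatter_add_cpp(dXc, g$idx0, g$K, g$P, g$C * g$Hp * g$Wp)
  dim(dxp) <- c(g$C, g$Hp, g$Wp, N)
  if (g$Hp != g$H || g$Wp != g$W) {
    ph <- (g$Hp - g$H) %/% 2L; pw <- (g$Wp - g$W) %/% 2L
    dxp <- dxp[, ph + seq_len(g$H), pw + seq_len(g$W), , drop = FALSE]
  }
  list(dx = dxp, grads = list(W = dW, b = db))
}

ly_backward.nn_maxpool <- function(layer, dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  oH <- d[2] %/% layer$ph; oW <- d[3] %/% layer$pw
  o <- 0L
  for (dw in seq_len(layer$pw)) for (dh in seq_len(layer$ph)) {
    o <- o + 1L
    sel <- cache$arg == o
    contrib <- dout * sel
    ih <- seq(dh, by = layer$ph, length.out = oH)
    iw <- seq(dw, by = layer$pw, length.out = oW)
    dx[, ih, iw, ] <- dx[, ih, iw, , drop = FALSE] + contrib
  }
  list(dx = dx, grads = NULL)
}

ly_backward.nn_avgpool <- function(layer, dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  oH <- d[2] %/% layer$ph; oW <- d[3] %/% layer$pw
  sc <- dout / (layer$ph * layer$pw)
  for (dw in seq_len(layer$pw)) for (dh in seq_len(layer$ph)) {
    ih <- seq(dh, by = layer$ph, length.out = oH)
    iw <- seq(dw, by = layer$pw, length.out = oW)
    dx[, ih, iw, ] <- dx[, ih, iw, , drop = FALSE] + sc
  }
  list(dx = dx, grads = NULL)
}

ly_backward.nn_batchnorm <- function(layer, dout, cache) {
  d <- cache$dims; C <- d[1]
  dim(dout) <- c(C, length(dout) %/% C)
  M <- ncol(dout)
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  if (cache$training) {
    dx <- (layer$par$gamma * cache$ivar) *
      (dout - dbeta / M - cache$xhat * (dgamma / M))
  } else {
    dx <- (layer$par$gamma * cache$ivar) * dout
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

ly_backward.nn_relu <- function(layer, dout, cache) {
  list(dx = dout * (cache$x > 0), grads = NULL)
}

ly_backward.nn_dropout <- function(layer, dout, cache) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = NULL))
  list(dx = dout * cache$mask, grads = NULL)
}

ly_backward.nn_flatten <- function(layer, dout, cache) {
  dim(dout) <- cache$dims
  list(dx = dout, grads = NULL)
}

ly_backward.nn_dense <- function(layer, dout, cache) {
  list(dx = crossprod(layer$par$W, dout),
       grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
}

# ---- DeepLIFT rescale-rule multipliers -------------------------------------
# Multipliers are backpropagated for (x, reference) pairs evaluated in
# inference mode. Linear/affine layers reuse the gradient path; elementwise
# nonlinearities use the rescale rule m_in = m_out * (dy/dx_delta); maxpool
# routes multipliers to the argmax of the actual input (gradient-style).

ly_mult <- function(layer, m_out, cache_x, cache_r) UseMethod("ly_mult")

ly_mult.nn_conv2d <- function(layer, m_out, cache_x, cache_r) {
  g <- layer$geom
  N <- cache_x$N
  dim(m_out) <- c(layer$out_ch, g$P * N)
  dXc <- crossprod(layer$par$W, m_out)
  dxp <- scatter_add_cpp(dXc, g$idx0, g$K, g$P, g$C * g$Hp * g$Wp)
  dim(dxp) <- c(g$C, g$Hp, g$Wp, N)
  if (g$Hp != g$H || g$Wp != g$W) {
    ph <- (g$Hp - g$H) %/% 2L; pw <- (g$Wp - g$W) %/% 2L
    dxp <- dxp[, ph + seq_len(g$H), pw + seq_len(g$W), , drop = FALSE]
  }
  dxp
}

ly_mult.nn_dense <- function(layer, m_out, cache_x, cache_r) {
  crossprod(layer$par$W, m_out)
}

ly_mult.nn_batchnorm <- function(layer, m_out, cache_x, cache_r) {
  d <- cache_x$dims; C <- d[1]
  dim(m_out) <- c(C, length(m_out) %/% C)
  m <- (layer$par$gamma * cache_x$ivar) * m_out
  dim(m) <- d
  m
}

ly_mult.nn_relu <- function(layer, m_out, cache_x, cache_r) {
  dx_in <- cache_x$x - cache_r$x
  dy <- pmax(cache_x$x, 0) - pmax(cache_r$x, 0)
  ratio <- ifelse(abs(dx_in) < 1e-7, (cache_x$x > 0) * 1, dy / dx_in)
  m_out * ratio
}

ly_mult.nn_maxpool <- function(layer, m_out, cache_x, cache_r) {
  # gradient-style routing to the argmax of the actual input (the standard
  # deep-explainer treatment of max pooling); completeness becomes
  # approximate wherever the argmax differs between input and reference
  ly_backward(layer, m_out, cache_x)$dx
}

ly_mult.nn_avgpool <- function(layer, m_out, cache_x, cache_r) {
  ly_backward(layer, m_out, cache_x)$dx
}

ly_mult.nn_dropout <- function(layer, m_out, cache_x, cache_r) m_out

ly_mult.nn_flatten <- function(layer, m_out, cache_x, cache_r) {
  dim(m_out) <- cache_x$dims
  m_out
}

# ---- parameter counting ----------------------------------------------------

ly_nparams <- function(layer) {
  if (is.null(layer$par)) return(0L)
  n <- 0L
  for (nm in names(layer$par)) {
    p <- layer$par[[nm]]
    if (nm == "W" && !is.null(layer$mask)) n <- n + sum(layer$mask != 0)
    else n <- n + length(p)
  }
  as.integer(n)
}

# ---- network container -----------------------------------------------------

#' Assemble a sequential network with shape inference
#'
#' Builds every layer (weight init uses the current RNG state) and records
#' per-layer input/output shapes for the fixed trial-tensor geometry.
#'
#' @param input_shape integer vector `(channels, height, width)` or a single
#'   feature count for dense-only networks
#' @param layers list of layer specs created by the `nn_*` constructors
#' @keywords internal
nn_network <- function(input_shape, layers) {
  shape <- input_shape
  built <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    built[[i]] <- ly_build(layers[[i]], shape)
    shape <- built[[i]]$out_shape
  }
  structure(list(layers = built, input_shape = input_shape, output_shape = shape),
            class = "ssml_network")
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- ly_forward(net$layers[[i]], x, training = training)
    x <- fw$out
    caches[[i]] <- fw$cache
    net$layers[[i]] <- fw$layer
  }
  list(out = x, caches = caches, net = net)
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- ly_backward(net$layers[[i]], dout, caches[[i]])
    dout <- bw$dx
    grads[i] <- list(bw$grads)
  }
  list(dx = dout, grads = grads)
}

# Backpropagate DeepLIFT multipliers through the net for an (input, reference)
# pair already forwarded in inference mode (caches_x, caches_r).
nn_multipliers <- function(net, caches_x, caches_r, m_out) {
  for (i in rev(seq_along(net$layers))) {
    m_out <- ly_mult(net$layers[[i]], m_out, caches_x[[i]], caches_r[[i]])
  }
  m_out
}

nn_update_sgd <- function(net, grads, lr, vel = NULL, momentum = 0) {
  if (is.null(vel)) vel <- lapply(grads, function(g) if (is.null(g)) NULL else lapply(g, function(x) x * 0))
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      vel[[i]][[nm]] <- momentum * vel[[i]][[nm]] - lr * grads[[i]][[nm]]
      net$layers[[i]]$par[[nm]] <- net$layers[[i]]$par[[nm]] + vel[[i]][[nm]]
    }
  }
  list(net = net, vel = vel)
}

#' Count trainable parameters of a network or a list of networks
#'
#' Masked (structurally zero) weights of depthwise/grouped convolutions are
#' excluded; batch-norm running statistics are not trainable and not counted.
#'
#' @param model an `ssml_network`, or a list whose elements are `ssml_network`s
#'   (e.g. a checkpoint with encoders and heads)
#' @return integer number of trainable scalars
#' @export
count_parameters <- function(model) {
  if (inherits(model, "ssml_network"))
    return(sum(vapply(model$layers, ly_nparams, integer(1))))
  if (is.list(model))
    return(sum(vapply(Filter(function(m) inherits(m, "ssml_network"), model),
                      count_parameters, integer(1))))
  stop("not a network or list of networks")
}

#' @export
print.ssml_network <- function(x, ...) {
  cat("ssml_network:", length(x$layers), "layers, ",
      count_parameters(x), "trainable parameters\n")
  for (l in x$layers) {
    cat(sprintf("  %-10s out=%s params=%d\n", l$type,
                paste(l$out_shape, collapse = "x"), ly_nparams(l)))
  }
  invisible(x)
}

# numerically stable helpers shared across modules
softmax_cols <- function(z, temperature = 1) {
  z <- z / temperature
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
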