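# Native NN layer framework: 4-D feature maps stored as arrays with dim
# (channels, height, width, batch). Channel-first with channels fastest lets
# per-channel broadcasts use plain R recycling, and im2col reduces every
# convolution to one BLAS matmul. Each layer is an environment carrying its
# parameters, gradients and forward caches; nn_forward()/nn_backward() are S3
# generics dispatched on the layer class.

#' Construct a feature map
#'
#' Wraps a numeric array into the (channels, height, width, batch) layout used
#' by every layer in the package. All entries must be finite.
#'
#' @param data numeric array or vector.
#' @param channels,height,width,batch dimensions; inferred when `data` already
#'   has a 4-D dim attribute.
#' @return a 4-D array of class `feature_map`.
#' @export
feature_map <- function(data, channels = NULL, height = NULL, width = NULL,
                        batch = 1L) {
  if (is.null(dim(data)) || length(dim(data)) != 4L) {
    stopifnot(!is.null(channels), !is.null(height), !is.null(width))
    data <- array(as.numeric(data), dim = c(channels, height, width, batch))
  }
  if (any(!is.finite(data))) stop("feature_map: all entries must be finite")
  if (dim(data)[2] < 1L || dim(data)[3] < 1L)
    stop("feature_map: height and width must be >= 1")
  structure(data, class = c("feature_map", "array"))
}

fm_dims <- function(x) {
  d <- dim(x)
  list(c = d[1], h = d[2], w = d[3], b = d[4])
}

as_fm <- function(x) {
  class(x) <- c("feature_map", "array")
  x
}

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

#' Forward pass through a layer or composite module
#'
#' @param layer a layer object created by one of the constructors.
#' @param x input feature map, dim (channels, height, width, batch).
#' @param train logical; training mode (batch statistics, caches kept).
#' @return output feature map.
#' @export
nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")

#' Backward pass; accumulates parameter gradients, returns input gradient
#'
#' Must be called after `nn_forward(..., train = TRUE)` on the same layer.
#'
#' @param layer layer object.
#' @param dy gradient of the loss w.r.t. the layer output.
#' @return gradient w.r.t. the layer input.
#' @export
nn_backward <- function(layer, dy) UseMethod("nn_backward")

#' List parameter tensors of a module (recursively)
#'
#' @param layer layer object.
#' @return list of environments, each with fields `$value`, `$grad`, `$decay`.
#' @export
nn_params <- function(layer) UseMethod("nn_params")

#' @export
nn_params.default <- function(layer) list()

# A parameter is its own tiny environment so optimizers can update in place.
new_param <- function(value, decay = FALSE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0      # same shape (and dim attributes) as the value
  p$mom <- NULL
  p$decay <- decay
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(layer) {
  for (p in nn_params(layer)) p$grad[] <- 0
  invisible(layer)
}

# Kaiming-uniform fan-in initialization, the convention of the YOLO family.
kaiming_uniform <- function(dims, fan_in, gain = sqrt(2)) {
  bound <- gain * sqrt(3 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

## ---- conv2d ----------------------------------------------------------------

#' Plain 2-D convolution layer (supports stride, dilation, depthwise groups)
#'
#' Weights are stored as a (in_c/groups * k * k) x out_c matrix so that the
#' forward pass is a single `crossprod` against the im2col matrix. Padding
#' defaults to `dilation * (kernel - 1) / 2`, which preserves the spatial
#' shape at stride 1 for any dilation.
#'
#' @param in_c,out_c channel counts.
#' @param kernel odd kernel size.
#' @param stride,dilation integers >= 1.
#' @param groups 1 (dense) or `in_c` (depthwise).
#' @param bias include a bias term.
#' @param pad padding; defaults to shape-preserving.
#' @export
conv2d <- function(in_c, out_c, kernel = 1L, stride = 1L, dilation = 1L,
                   groups = 1L, bias = TRUE, pad = NULL) {
  if (kernel %% 2L == 0L) stop("conv2d: kernel size must be odd")
  if (dilation < 1L) stop("conv2d: dilation must be >= 1")
  if (in_c %% groups != 0L || out_c %% groups != 0L)
    stop("conv2d: groups must divide both channel counts")
  if (groups != 1L && groups != in_c)
    stop("conv2d: only dense (groups=1) and depthwise (groups=in_c) supported")
  if (groups == in_c && out_c != in_c)
    stop("conv2d: depthwise requires out_c == in_c")
  if (is.null(pad)) pad <- dilation * (kernel - 1L) / 2L
  cg <- in_c / groups
  fan_in <- cg * kernel * kernel
  if (groups == 1L) {
    W <- new_param(kaiming_uniform(c(cg * kernel * kernel, out_c), fan_in),
                   decay = TRUE)
  } else {
    W <- new_param(kaiming_uniform(c(in_c, kernel, kernel), fan_in),
                   decay = TRUE)
  }
  b <- if (bias) new_param(numeric(out_c)) else NULL
  new_layer("conv2d", in_c = in_c, out_c = out_c, k = as.integer(kernel),
            stride = as.integer(stride), dil = as.integer(dilation),
            groups = as.integer(groups), pad = as.integer(pad), W = W, b = b,
            idx_cache = list())
}

# im2col gather index for the padded input of one image, in (c, ky, kx) row
# order by (oy, ox) column order.
conv_idx <- function(C, Hp, Wp, k, stride, dil, oh, ow) {
  kyo <- (0:(k - 1L)) * dil
  kxo <- (0:(k - 1L)) * dil
  oyo <- (0:(oh - 1L)) * stride
  oxo <- (0:(ow - 1L)) * stride
  cv  <- rep.int(seq_len(C), k * k * oh * ow)
  kyv <- rep.int(rep(kyo, each = C), k * oh * ow)
  kxv <- rep.int(rep(kxo, each = C * k), oh * ow)
  oyv <- rep.int(rep(oyo, each = C * k * k), ow)
  oxv <- rep(oxo, each = C * k * k * oh)
  cv + C * (kyv + oyv) + C * Hp * (kxv + oxv)
}

pad_input <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  xp[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  xp
}

#' @export
nn_forward.conv2d <- function(layer, x, train = FALSE) {
  d <- dim(x)
  stopifnot(d[1] == layer$in_c)
  p <- layer$pad; k <- layer$k; s <- layer$stride; dl <- layer$dil
  oh <- (d[2] + 2L * p - dl * (k - 1L) - 1L) %/% s + 1L
  ow <- (d[3] + 2L * p - dl * (k - 1L) - 1L) %/% s + 1L
  xp <- pad_input(x, p)
  dp <- dim(xp)
  if (layer$groups == 1L) {
    key <- paste(dp[2], dp[3], oh, ow, sep = "x")
    idx <- layer$idx_cache[[key]]
    if (is.null(idx)) {
      idx <- conv_idx(d[1], dp[2], dp[3], k, s, dl, oh, ow)
      layer$idx_cache[[key]] <- idx
    }
    n1 <- dp[1] * dp[2] * dp[3]
    ncolb <- oh * ow
    y <- array(0, dim = c(layer$out_c, oh, ow, d[4]))
    cols <- vector("list", d[4])
    for (bi in seq_len(d[4])) {
      col <- xp[idx + (bi - 1L) * n1]
      dim(col) <- c(d[1] * k * k, ncolb)
      cols[[bi]] <- col
      y[, , , bi] <- crossprod(layer$W$value, col)
    }
    if (train) { layer$cols <- cols; layer$in_dim <- d; layer$out_hw <- c(oh, ow) }
  } else {
    # depthwise: k^2 shifted channelwise multiplies (vectorized over channels)
    y <- array(0, dim = c(layer$out_c, oh, ow, d[4]))
    Wv <- layer$W$value
    for (ky in seq_len(k)) for (kx in seq_len(k)) {
      ys <- (0:(oh - 1L)) * s + (ky - 1L) * dl + 1L
      xs <- (0:(ow - 1L)) * s + (kx - 1L) * dl + 1L
      y <- y + xp[, ys, xs, , drop = FALSE] * Wv[, ky, kx]
    }
    if (train) { layer$xp <- xp; layer$in_dim <- d; layer$out_hw <- c(oh, ow) }
  }
  if (!is.null(layer$b)) y <- y + layer$b$value
  as_fm(y)
}

#' @export
nn_backward.conv2d <- function(layer, dy) {
  d <- layer$in_dim
  p <- layer$pad; k <- layer$k; s <- layer$stride; dl <- layer$dil
  oh <- layer$out_hw[1]; ow <- layer$out_hw[2]
  Hp <- d[2] + 2L * p; Wp <- d[3] + 2L * p
  if (!is.null(layer$b)) {
    db <- rowSums(dy, dims = 1L)
    layer$b$grad <- layer$b$grad + db
  }
  dxp <- array(0, dim = c(d[1], Hp, Wp, d[4]))
  if (layer$groups == 1L) {
    Wm <- layer$W$value
    for (bi in seq_len(d[4])) {
      dym <- matrix(dy[, , , bi], nrow = layer$out_c)
      layer$W$grad <- layer$W$grad + layer$cols[[bi]] %*% t(dym)
      dcol <- Wm %*% dym                      # (C*k*k) x (oh*ow)
      dim(dcol) <- c(d[1], k, k, oh, ow)
      for (ky in seq_len(k)) for (kx in seq_len(k)) {
        ys <- (0:(oh - 1L)) * s + (ky - 1L) * dl + 1L
        xs <- (0:(ow - 1L)) * s + (kx - 1L) * dl + 1L
        dxp[, ys, xs, bi] <- dxp[, ys, xs, bi] + dcol[, ky, kx, , ]
      }
    }
    layer$cols <- NULL
  } else {
    Wv <- layer$W$value
    xp <- layer$xp
    for (ky in seq_len(k)) for (kx in seq_len(k)) {
      ys <- (0:(oh - 1L)) * s + (ky - 1L) * dl + 1L
      xs <- (0:(ow - 1L)) * s + (kx - 1L) * dl + 1L
      xs_sl <- xp[, ys, xs, , drop = FALSE]
      layer$W$grad[, ky, kx] <- layer$W$grad[, ky, kx] +
        rowSums(dy * xs_sl, dims = 1L)
      dxp[, ys, xs, ] <- dxp[, ys, xs, , drop = FALSE] + dy * Wv[, ky, kx]
    }
    layer$xp <- NULL
  }
  if (p > 0L) dxp <- dxp[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ,
                         drop = FALSE]
  dxp
}

#' @export
nn_params.conv2d <- function(layer) {
  if (is.null(layer$b)) list(layer$W) else list(layer$W, layer$b)
}

## ---- batch normalization ---------------------------------------------------

#' 2-D batch normalization (per-channel)
#' @param c channel count.
#' @param eps,momentum numerical constants (YOLOv5 defaults).
#' @export
batchnorm2d <- function(c, eps = 1e-3, momentum = 0.03) {
  new_layer("batchnorm2d", nch = c, eps = eps, momentum = momentum,
            gamma = new_param(rep(1, c)), beta = new_param(rep(0, c)),
            run_mean = rep(0, c), run_var = rep(1, c))
}

#' @export
nn_forward.batchnorm2d <- function(layer, x, train = FALSE) {
  d <- dim(x)
  n <- d[2] * d[3] * d[4]
  if (train) {
    mu <- rowSums(x, dims = 1L) / n
    xc <- x - mu
    v <- rowSums(xc * xc, dims = 1L) / n
    ivar <- 1 / sqrt(v + layer$eps)
    xhat <- xc * ivar
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var +
      layer$momentum * v * n / max(n - 1, 1)
    layer$xhat <- xhat; layer$ivar <- ivar; layer$n <- n
  } else {
    ivar <- 1 / sqrt(layer$run_var + layer$eps)
    xhat <- (x - layer$run_mean) * ivar
  }
  as_fm(xhat * layer$gamma$value + layer$beta$value)
}

#' @export
nn_backward.batchnorm2d <- function(layer, dy) {
  xhat <- layer$xhat; ivar <- layer$ivar; n <- layer$n
  g <- layer$gamma$value
  layer$gamma$grad <- layer$gamma$grad + rowSums(dy * xhat, dims = 1L)
  layer$beta$grad <- layer$beta$grad + rowSums(dy, dims = 1L)
  dxhat <- dy * g
  s1 <- rowSums(dxhat, dims = 1L)
  s2 <- rowSums(dxhat * xhat, dims = 1L)
  dx <- ivar * (dxhat - s1 / n - xhat * (s2 / n))
  layer$xhat <- NULL
  dx
}

#' @export
nn_params.batchnorm2d <- function(layer) list(layer$gamma, layer$beta)

## ---- activations -----------------------------------------------------------

#' SiLU (swish) activation layer
#' @export
act_silu <- function() new_layer("act_silu")

#' @export
nn_forward.act_silu <- function(layer, x, train = FALSE) {
  s <- 1 / (1 + exp(-x))
  if (train) { layer$x <- x; layer$s <- s }
  as_fm(x * s)
}

#' @export
nn_backward.act_silu <- function(layer, dy) {
  s <- layer$s; x <- layer$x
  dx <- dy * (s * (1 + x * (1 - s)))
  layer$x <- NULL; layer$s <- NULL
  dx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- pooling / resampling --------------------------------------------------

#' Max pooling with 'same' padding (stride 1), as used by the SPP pyramid
#' @param k odd kernel size.
#' @export
maxpool_same <- function(k) {
  new_layer("maxpool_same", k = as.integer(k), pad = as.integer((k - 1) / 2))
}

#' @export
nn_forward.maxpool_same <- function(layer, x, train = FALSE) {
  d <- dim(x)
  k <- layer$k; p <- layer$pad
  xp <- array(-Inf, dim = c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  xp[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  y <- array(-Inf, dim = d)
  arg <- array(1L, dim = d)
  o <- 0L
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    o <- o + 1L
    cand <- xp[, ky:(ky + d[2] - 1L), kx:(kx + d[3] - 1L), , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- o
  }
  if (train) { layer$arg <- arg; layer$in_dim <- d }
  as_fm(y)
}

#' @export
nn_backward.maxpool_same <- function(layer, dy) {
  d <- layer$in_dim
  k <- layer$k; p <- layer$pad
  dxp <- array(0, dim = c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  o <- 0L
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    o <- o + 1L
    m <- dy * (layer$arg == o)
    dxp[, ky:(ky + d[2] - 1L), kx:(kx + d[3] - 1L), ] <-
      dxp[, ky:(ky + d[2] - 1L), kx:(kx + d[3] - 1L), , drop = FALSE] + m
  }
  layer$arg <- NULL
  dxp[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), , drop = FALSE]
}

#' Nearest-neighbour 2x upsampling layer
#' @export
upsample2x <- function() new_layer("upsample2x")

#' @export
nn_forward.upsample2x <- function(layer, x, train = FALSE) {
  d <- dim(x)
  if (train) layer$in_dim <- d
  as_fm(x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
          drop = FALSE])
}

#' @export
nn_backward.upsample2x <- function(layer, dy) {
  d <- layer$in_dim
  ey <- seq_len(d[2]) * 2L; oy <- ey - 1L
  ex <- seq_len(d[3]) * 2L; ox <- ex - 1L
  dy[, oy, ox, , drop = FALSE] + dy[, oy, ex, , drop = FALSE] +
    dy[, ey, ox, , drop = FALSE] + dy[, ey, ex, , drop = FALSE]
}

# global average pool: (C,H,W,B) -> (C,1,1,B)
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- array(0, dim = c(d[1], 1L, 1L, d[4]))
  for (bi in seq_len(d[4])) out[, 1L, 1L, bi] <- rowMeans(m[, , bi, drop = FALSE], dims = 1L)
  out
}

gap_backward <- function(dg, in_dim) {
  # dg: (C,1,1,B) -> broadcast /HW
  hw <- in_dim[2] * in_dim[3]
  dx <- array(0, dim = in_dim)
  for (bi in seq_len(in_dim[4])) {
    dx[, , , bi] <- array(rep(dg[, 1L, 1L, bi] / hw, in_dim[2] * in_dim[3]),
                          dim = in_dim[1:3])
  }
  dx
}

## ---- sequential composite --------------------------------------------------

#' Sequential composite of layers
#' @param ... layers, applied in order.
#' @export
nn_sequential <- function(...) {
  new_layer("nn_sequential", layers = list(...))
}

#' @export
nn_forward.nn_sequential <- function(layer, x, train = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, train)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, dy) {
  for (l in rev(layer$layers)) dy <- nn_backward(l, dy)
  dy
}

#' @export
nn_params.nn_sequential <- function(layer) {
  unlist(lapply(layer$layers, nn_params), recursive = FALSE)
}

#' Conv + batch norm + SiLU block (the YOLOv5 `Conv` unit)
#' @inheritParams conv2d
#' @export
conv_block <- function(in_c, out_c, kernel = 1L, stride = 1L, dilation = 1L,
                       groups = 1L, pad = NULL) {
  l <- nn_sequential(
    conv2d(in_c, out_c, kernel, stride, dilation, groups, bias = FALSE,
           pad = pad),
    batchnorm2d(out_c),
    act_silu())
  class(l) <- c("conv_block", class(l))
  l
}

## ---- optimizer -------------------------------------------------------------

#' One SGD step with momentum and (optional) weight decay
#'
#' @param params list from [nn_params()].
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 decay applied to parameters flagged `decay`
#'   (convolution kernels), never to norm scales or biases.
#' @export
sgd_step <- function(params, lr, momentum = 0.937, weight_decay = 0) {
  for (p in params) {
    g <- p$grad
    if (weight_decay > 0 && isTRUE(p$decay)) g <- g + weight_decay * p$value
    if (is.null(p$mom)) p$mom <- p$value * 0
    p$mom <- momentum * p$mom + g
    p$value <- p$value - lr * p$mom
    p$grad[] <- 0
  }
  invisible(NULL)
}

## ---- traversal -------------------------------------------------------------

#' Enumerate direct sub-layers of a composite module
#' @param layer module.
#' @return list of child layers (empty for leaves).
#' @export
nn_children <- function(layer) UseMethod("nn_children")

#' @export
nn_children.default <- function(layer) list()

#' @export
nn_children.nn_sequential <- function(layer) layer$layers

# all leaves of a module tree, depth first
nn_leaves <- function(layer) {
  ch <- nn_children(layer)
  if (length(ch) == 0L) return(list(layer))
  unlist(lapply(ch, nn_leaves), recursive = FALSE)
}

## ---- weight (de)serialization ---------------------------------------------

#' Extract all parameter values and norm statistics of a module
#' @param layer module.
#' @return list with `weights` (numeric arrays, ordered as [nn_params()]) and
#'   `bn_stats` (running mean/var per batch-norm leaf).
#' @export
get_weights <- function(layer) {
  bn <- Filter(function(l) inherits(l, "batchnorm2d"), nn_leaves(layer))
  list(weights = lapply(nn_params(layer), function(p) p$value),
       bn_stats = lapply(bn, function(l) list(mean = l$run_mean,
                                              var = l$run_var)))
}

#' Load parameter values produced by [get_weights()]
#' @param layer module.
#' @param state list from [get_weights()].
#' @export
set_weights <- function(layer, state) {
  ps <- nn_params(layer)
  w <- state$weights
  stopifnot(length(ps) == length(w))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$value) == length(w[[i]]))
    ps[[i]]$value[] <- w[[i]]
  }
  bn <- Filter(function(l) inherits(l, "batchnorm2d"), nn_leaves(layer))
  stopifnot(length(bn) == length(state$bn_stats))
  for (i in seq_along(bn)) {
    bn[[i]]$run_mean <- state$bn_stats[[i]]$mean
    bn[[i]]$run_var <- state$bn_stats[[i]]$var
  }
  invisible(layer)
}
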