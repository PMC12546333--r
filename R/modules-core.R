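# Backbone-tail module family: atrous spatial pyramid pooling (standard and
# depthwise-separable lightweight forms), CBAM-style channel/spatial attention
# (standard and simplified), and the seven composable tail variants used in
# the ablation grid. Every variant is shape preserving: the spatial extent of
# the output always equals that of the input.

#' Registry of backbone-tail variant names
#' @export
VARIANT_NAMES <- c("SPP", "ASPP", "LASPP", "APCM", "LAPCM", "LLAAM", "LAAM")

# variant -> (attention, residual) composition, fixed by the ablation design
variant_composition <- function(variant) {
  switch(variant,
    SPP   = list(aspp = "none",     attention = "none",            residual = "none"),
    ASPP  = list(aspp = "standard", attention = "none",            residual = "none"),
    LASPP = list(aspp = "light",    attention = "none",            residual = "none"),
    APCM  = list(aspp = "standard", attention = "standard_cbam",   residual = "identity"),
    LAPCM = list(aspp = "standard", attention = "standard_cbam",   residual = "none"),
    LLAAM = list(aspp = "light",    attention = "simplified_cbam", residual = "none"),
    LAAM  = list(aspp = "light",    attention = "simplified_cbam", residual = "projected_sum"),
    stop("unknown variant '", variant, "'; valid names: ",
         paste(VARIANT_NAMES, collapse = ", ")))
}

#' Declarative description of one backbone-tail variant
#'
#' The attention and residual fields are determined by the variant name
#' (the ablation grid is fixed); supplying conflicting values is an error.
#'
#' @param variant one of `r paste(VARIANT_NAMES, collapse=", ")`.
#' @param in_channels,out_channels channel widths of the tail slot.
#' @param dilation_rates dilation rates of the 3x3 atrous branches.
#' @param channel_reduction bottleneck reduction of the channel attention.
#' @param branch_width_ratio each parallel branch outputs
#'   `round(in_channels * branch_width_ratio)` channels. The default is the
#'   package's calibrated value (see the methods vignette).
#' @param attention,residual optional; must agree with the variant.
#' @param spatial_attention_input `"pooled"` (channel mean/max maps, default)
#'   or `"full"` (full channel depth) for the simplified spatial attention.
#' @return a `module_spec` list.
#' @export
module_spec <- function(variant, in_channels, out_channels = in_channels,
                        dilation_rates = c(6L, 12L), channel_reduction = 16L,
                        branch_width_ratio = laam_options()$branch_width_ratio,
                        attention = NULL, residual = NULL,
                        spatial_attention_input = "pooled") {
  variant <- match.arg(variant, VARIANT_NAMES)
  comp <- variant_composition(variant)
  if (!is.null(attention) && !identical(attention, comp$attention))
    stop("module_spec: variant ", variant, " requires attention = '",
         comp$attention, "'")
  if (!is.null(residual)) {
    res_name <- if (identical(residual, "projected_sum")) "projected_sum" else residual
    if (variant == "LAAM" && !identical(res_name, "projected_sum"))
      stop("module_spec: LAAM requires residual = 'projected_sum'")
    if (variant %in% c("LASPP", "LLAAM", "LAPCM", "ASPP", "SPP") &&
        !identical(res_name, "none"))
      stop("module_spec: variant ", variant, " requires residual = 'none'")
  }
  if (length(dilation_rates) < 2L && comp$aspp != "none")
    stop("module_spec: at least 2 dilation rates are required")
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rates = as.integer(dilation_rates),
                 attention = comp$attention, residual = comp$residual,
                 channel_reduction = as.integer(channel_reduction),
                 branch_width_ratio = branch_width_ratio,
                 spatial_attention_input = match.arg(spatial_attention_input,
                                                     c("pooled", "full"))),
            class = "module_spec")
}

#' Serialize / read a module spec as a YAML block
#' @param spec a `module_spec`.
#' @return YAML text.
#' @export
module_spec_yaml <- function(spec) yaml::as.yaml(unclass(spec))

#' @rdname module_spec_yaml
#' @param text YAML text produced by [module_spec_yaml()].
#' @export
module_spec_from_yaml <- function(text) {
  v <- yaml::yaml.load(text)
  module_spec(v$variant, v$in_channels, v$out_channels,
              dilation_rates = v$dilation_rates,
              channel_reduction = v$channel_reduction,
              branch_width_ratio = v$branch_width_ratio,
              spatial_attention_input = v$spatial_attention_input %||% "pooled")
}

## ---- depthwise separable convolution --------------------------------------

#' Depthwise separable convolution block
#'
#' A per-channel (depthwise) dilated convolution followed by a 1x1 pointwise
#' convolution, each followed by batch normalization (optional) and a
#' nonlinearity. Spatial shape is preserved for any dilation.
#'
#' @param in_c,out_c channel counts.
#' @param kernel odd kernel size.
#' @param dilation dilation rate of the depthwise stage.
#' @param norm include batch normalization (when `FALSE` the convolutions
#'   carry bias terms instead).
#' @param act nonlinearity: `"silu"` (default), `"relu"`, or `"none"`.
#' @export
ds_conv <- function(in_c, out_c, kernel = 3L, dilation = 1L, norm = TRUE,
                    act = "silu") {
  act <- match.arg(act, c("silu", "relu", "none"))
  mk_act <- function() switch(act, silu = list(act_silu()),
                              relu = list(act_relu()), none = list())
  mk_norm <- function(c) if (norm) list(batchnorm2d(c)) else list()
  layers <- c(
    list(conv2d(in_c, in_c, kernel, dilation = dilation, groups = in_c,
                bias = !norm)),
    mk_norm(in_c), mk_act(),
    list(conv2d(in_c, out_c, 1L, bias = !norm)),
    mk_norm(out_c), mk_act())
  l <- do.call(nn_sequential, layers)
  class(l) <- c("ds_conv", class(l))
  l
}

#' ReLU activation layer
#' @export
act_relu <- function() new_layer("act_relu")

#' @export
nn_forward.act_relu <- function(layer, x, train = FALSE) {
  if (train) layer$mask <- x > 0
  as_fm(x * (x > 0))
}

#' @export
nn_backward.act_relu <- function(layer, dy) {
  m <- dy * layer$mask
  layer$mask <- NULL
  m
}

## ---- channel attention ------------------------------------------------------

#' Channel attention (standard: GAP + two fully connected layers)
#'
#' Produces one sigmoid weight per channel, strictly in (0, 1).
#'
#' @param c channel count.
#' @param reduction bottleneck reduction ratio; must divide `c` and not
#'   exceed it.
#' @export
channel_attention_standard <- function(c, reduction = 16L) {
  check_reduction(c, reduction)
  h <- c %/% reduction
  new_layer("chan_attn",
            nch = c, hidden = h, std = TRUE,
            W1 = new_param(kaiming_uniform(c(c, h), c), decay = TRUE),
            b1 = new_param(numeric(h)),
            W2 = new_param(kaiming_uniform(c(h, c), h), decay = TRUE),
            b2 = new_param(numeric(c)))
}

#' Channel attention (simplified: GAP + bias-free 1x1 bottleneck)
#'
#' Identical information flow to the standard form but the bottleneck omits
#' the bias terms, and its multiplies act on a 1x1 spatial extent.
#'
#' @inheritParams channel_attention_standard
#' @export
channel_attention_simplified <- function(c, reduction = 16L) {
  check_reduction(c, reduction)
  h <- c %/% reduction
  new_layer("chan_attn",
            nch = c, hidden = h, std = FALSE,
            W1 = new_param(kaiming_uniform(c(c, h), c), decay = TRUE),
            b1 = NULL,
            W2 = new_param(kaiming_uniform(c(h, c), h), decay = TRUE),
            b2 = NULL)
}

check_reduction <- function(c, reduction) {
  if (reduction > c) stop("channel attention: reduction exceeds channel count")
  if (c %% reduction != 0L) stop("channel attention: reduction must divide channels")
}

# forward returns weights with dim (C,1,1,B), class channel_weights
#' @export
nn_forward.chan_attn <- function(layer, x, train = FALSE) {
  d <- dim(x)
  g <- gap_forward(x)                      # (C,1,1,B)
  gm <- matrix(g, nrow = d[1])             # C x B
  h <- crossprod(layer$W1$value, gm)       # hidden x B
  if (!is.null(layer$b1)) h <- h + layer$b1$value
  hr <- h * (h > 0)
  z <- crossprod(layer$W2$value, hr)       # C x B
  if (!is.null(layer$b2)) z <- z + layer$b2$value
  w <- sigmoid(z)
  if (train) {
    layer$in_dim <- d; layer$gm <- gm; layer$h <- h; layer$hr <- hr
    layer$wv <- w
  }
  structure(array(w, dim = c(d[1], 1L, 1L, d[4])),
            class = c("channel_weights", "array"))
}

#' @export
nn_backward.chan_attn <- function(layer, dw) {
  # dw: gradient w.r.t. the (C,1,1,B) weights
  d <- layer$in_dim
  dz <- matrix(dw, nrow = d[1]) * layer$wv * (1 - layer$wv)
  if (!is.null(layer$b2)) layer$b2$grad <- layer$b2$grad + rowSums(dz)
  layer$W2$grad <- layer$W2$grad + layer$hr %*% t(dz)
  dhr <- layer$W2$value %*% dz
  dh <- dhr * (layer$h > 0)
  if (!is.null(layer$b1)) layer$b1$grad <- layer$b1$grad + rowSums(dh)
  layer$W1$grad <- layer$W1$grad + layer$gm %*% t(dh)
  dg <- layer$W1$value %*% dh              # C x B
  gap_backward(array(dg, dim = c(d[1], 1L, 1L, d[4])), d)
}

#' @export
nn_params.chan_attn <- function(layer) {
  Filter(Negate(is.null), list(layer$W1, layer$b1, layer$W2, layer$b2))
}

## ---- spatial attention -----------------------------------------------------

#' Spatial attention (standard: channel mean/max maps + 7x7 convolution)
#' @export
spatial_attention_standard <- function() {
  new_layer("spat_attn", k = 7L, pooled = TRUE, c_in = 2L,
            conv = conv2d(2L, 1L, 7L, bias = TRUE))
}

#' Spatial attention (simplified: 1x1 convolution)
#'
#' @param c_in input channel count; only used when `input = "full"`.
#' @param input `"pooled"` (channel mean/max maps, 2 channels in) or `"full"`
#'   (the whole channel depth).
#' @export
spatial_attention_simplified <- function(c_in = NULL, input = "pooled") {
  input <- match.arg(input, c("pooled", "full"))
  cin <- if (input == "pooled") 2L else as.integer(c_in)
  new_layer("spat_attn", k = 1L, pooled = input == "pooled", c_in = cin,
            conv = conv2d(cin, 1L, 1L, bias = TRUE))
}

channel_pool <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mean_map <- colMeans(xm)
  arg <- max.col(t(xm), ties.method = "first")
  max_map <- xm[cbind(arg, seq_len(ncol(xm)))]
  pooled <- array(0, dim = c(2L, d[2], d[3], d[4]))
  pooled[1L, , , ] <- mean_map
  pooled[2L, , , ] <- max_map
  list(pooled = pooled, arg = arg)
}

#' @export
nn_forward.spat_attn <- function(layer, x, train = FALSE) {
  d <- dim(x)
  if (layer$pooled) {
    cp <- channel_pool(x)
    z <- nn_forward(layer$conv, as_fm(cp$pooled), train)
    if (train) { layer$arg <- cp$arg; layer$in_dim <- d }
  } else {
    z <- nn_forward(layer$conv, x, train)
    if (train) layer$in_dim <- d
  }
  w <- sigmoid(z)
  if (train) layer$wv <- w
  structure(array(w, dim = dim(z)), class = c("spatial_weights", "array"))
}

#' @export
nn_backward.spat_attn <- function(layer, dw) {
  dz <- dw * layer$wv * (1 - layer$wv)
  dpool <- nn_backward(layer$conv, dz)
  if (!layer$pooled) { layer$wv <- NULL; return(dpool) }
  d <- layer$in_dim
  # mean map gradient spreads uniformly over channels
  dmean <- dpool[1L, , , , drop = FALSE] / d[1]
  dxm <- matrix(rep(as.numeric(dmean), each = d[1]), nrow = d[1])
  # max map gradient routes to the argmax channel
  dmaxv <- as.numeric(dpool[2L, , , ])
  idx <- cbind(layer$arg, seq_along(layer$arg))
  dxm[idx] <- dxm[idx] + dmaxv
  layer$arg <- NULL; layer$wv <- NULL
  array(dxm, dim = d)
}

#' @export
nn_params.spat_attn <- function(layer) nn_params(layer$conv)

## ---- CBAM composites -------------------------------------------------------

#' Standard CBAM: channel then spatial attention, sequentially multiplicative
#' @param c channel count of the gated features.
#' @param reduction channel-attention reduction ratio.
#' @export
cbam_standard <- function(c, reduction = 16L) {
  new_layer("attn_cbam", nch = c,
            chan = channel_attention_standard(c, reduction),
            spat = spatial_attention_standard())
}

#' @export
nn_forward.attn_cbam <- function(layer, x, train = FALSE) {
  cw <- nn_forward(layer$chan, x, train)
  y1 <- x * cw_expand(cw, dim(x))
  sw <- nn_forward(layer$spat, as_fm(y1), train)
  out <- y1 * sw_expand(sw, dim(x))
  if (train) { layer$x <- x; layer$cw <- cw; layer$y1 <- y1; layer$sw <- sw }
  as_fm(out)
}

#' @export
nn_backward.attn_cbam <- function(layer, dy) {
  x <- layer$x; cw <- layer$cw; y1 <- layer$y1; sw <- layer$sw
  d <- dim(x)
  swe <- sw_expand(sw, d)
  dy1 <- dy * swe
  dsw <- array(colSums(matrix(dy * y1, nrow = d[1])), dim = dim(sw))
  dy1 <- dy1 + nn_backward(layer$spat, dsw)
  cwe <- cw_expand(cw, d)
  dx <- dy1 * cwe
  dcw <- chan_weight_grad(dy1 * x, d)
  dx <- dx + nn_backward(layer$chan, dcw)
  layer$x <- NULL; layer$cw <- NULL; layer$y1 <- NULL; layer$sw <- NULL
  dx
}

#' @export
nn_params.attn_cbam <- function(layer) c(nn_params(layer$chan), nn_params(layer$spat))

#' @export
nn_children.attn_cbam <- function(layer) list(layer$chan, layer$spat)

# broadcast helpers: channel weights (C,1,1,B) and spatial weights (1,H,W,B)
cw_expand <- function(cw, d) {
  out <- array(0, dim = d)
  for (bi in seq_len(d[4])) out[, , , bi] <- cw[, 1L, 1L, bi]
  out
}

sw_expand <- function(sw, d) {
  out <- array(0, dim = d)
  for (bi in seq_len(d[4]))
    out[, , , bi] <- rep(sw[1L, , , bi], each = d[1])
  out
}

# sum over H,W of a (C,H,W,B) array -> (C,1,1,B)
chan_weight_grad <- function(a, d) {
  m <- a
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- array(0, dim = c(d[1], 1L, 1L, d[4]))
  for (bi in seq_len(d[4])) out[, 1L, 1L, bi] <- rowSums(m[, , bi, drop = FALSE], dims = 1L)
  out
}

#' Enhanced (simplified) CBAM with dilated context extraction
#'
#' The attention branch first enlarges its receptive field with two parallel
#' full-depth 3x3 dilated convolutions (rates `dilations`), sums them into a
#' context map, then derives simplified channel weights (GAP bottleneck) and a
#' simplified spatial weight map (1x1 convolution) from that context; both are
#' applied multiplicatively to the gated features.
#'
#' @param c channel count.
#' @param reduction channel-attention reduction.
#' @param dilations dilation rates of the context convolutions.
#' @param spatial_input `"pooled"` or `"full"` (see
#'   [spatial_attention_simplified()]).
#' @export
cbam_enhanced <- function(c, reduction = 16L, dilations = c(6L, 12L),
                          spatial_input = "pooled") {
  new_layer("attn_enhanced", nch = c,
            ctx1 = conv_block(c, c, 3L, dilation = dilations[1]),
            ctx2 = conv_block(c, c, 3L, dilation = dilations[2]),
            chan = channel_attention_simplified(c, reduction),
            spat = spatial_attention_simplified(c, input = spatial_input))
}

#' @export
nn_forward.attn_enhanced <- function(layer, x, train = FALSE) {
  ctx <- nn_forward(layer$ctx1, x, train) + nn_forward(layer$ctx2, x, train)
  cw <- nn_forward(layer$chan, as_fm(ctx), train)
  sw <- nn_forward(layer$spat, as_fm(ctx), train)
  d <- dim(x)
  out <- x * cw_expand(cw, d) * sw_expand(sw, d)
  if (train) { layer$x <- x; layer$cw <- cw; layer$sw <- sw }
  as_fm(out)
}

#' @export
nn_backward.attn_enhanced <- function(layer, dy) {
  x <- layer$x; cw <- layer$cw; sw <- layer$sw
  d <- dim(x)
  cwe <- cw_expand(cw, d); swe <- sw_expand(sw, d)
  dx <- dy * cwe * swe
  dcw <- chan_weight_grad(dy * x * swe, d)
  dsw <- array(colSums(matrix(dy * x * cwe, nrow = d[1])), dim = dim(sw))
  dctx <- nn_backward(layer$chan, dcw) + nn_backward(layer$spat, dsw)
  dx <- dx + nn_backward(layer$ctx1, dctx) + nn_backward(layer$ctx2, dctx)
  layer$x <- NULL; layer$cw <- NULL; layer$sw <- NULL
  dx
}

#' @export
nn_params.attn_enhanced <- function(layer) {
  c(nn_params(layer$ctx1), nn_params(layer$ctx2),
    nn_params(layer$chan), nn_params(layer$spat))
}

#' @export
nn_children.attn_enhanced <- function(layer) {
  list(layer$ctx1, layer$ctx2, layer$chan, layer$spat)
}

## ---- ASPP blocks -----------------------------------------------------------

#' Standard atrous spatial pyramid pooling block
#'
#' Four parallel branches (1x1 convolution; one 3x3 atrous convolution per
#' dilation rate; global average pool + 1x1 convolution broadcast back to the
#' input extent), concatenated and fused by a 1x1 convolution.
#'
#' @param spec a [module_spec()] whose variant uses the standard form.
#' @export
aspp_standard <- function(spec) {
  if (!spec$variant %in% c("ASPP", "APCM", "LAPCM"))
    stop("aspp_standard: spec variant must be ASPP, APCM or LAPCM")
  if (length(spec$dilation_rates) < 2L)
    stop("aspp_standard: at least 2 dilation rates required")
  c1 <- spec$in_channels
  b <- max(1L, as.integer(round(c1 * spec$branch_width_ratio)))
  dil_branches <- lapply(spec$dilation_rates, function(r)
    conv_block(c1, b, 3L, dilation = r))
  nb <- 2L + length(dil_branches)
  new_layer("aspp_std", b = b, nb = nb,
            br1 = conv_block(c1, b, 1L),
            brd = dil_branches,
            brg = conv_block(c1, b, 1L),
            fuse = conv_block(nb * b, spec$out_channels, 1L))
}

#' @export
nn_forward.aspp_std <- function(layer, x, train = FALSE) {
  d <- dim(x)
  b <- layer$b
  outs <- vector("list", layer$nb)
  outs[[1]] <- nn_forward(layer$br1, x, train)
  for (i in seq_along(layer$brd))
    outs[[1 + i]] <- nn_forward(layer$brd[[i]], x, train)
  g <- gap_forward(x)
  gi <- nn_forward(layer$brg, as_fm(g), train)
  gb <- array(0, dim = c(b, d[2], d[3], d[4]))
  for (bi in seq_len(d[4])) gb[, , , bi] <- gi[, 1L, 1L, bi]
  outs[[layer$nb]] <- gb
  cat_x <- array(0, dim = c(layer$nb * b, d[2], d[3], d[4]))
  for (i in seq_len(layer$nb))
    cat_x[((i - 1L) * b + 1L):(i * b), , , ] <- outs[[i]]
  if (train) { layer$in_dim <- d; layer$cat_pre <- NULL }
  nn_forward(layer$fuse, as_fm(cat_x), train)
}

#' @export
nn_backward.aspp_std <- function(layer, dy) {
  d <- layer$in_dim
  b <- layer$b
  dcat <- nn_backward(layer$fuse, dy)
  dx <- nn_backward(layer$br1, dcat[1:b, , , , drop = FALSE])
  for (i in seq_along(layer$brd)) {
    sl <- dcat[(i * b + 1L):((i + 1L) * b), , , , drop = FALSE]
    dx <- dx + nn_backward(layer$brd[[i]], sl)
  }
  gsl <- dcat[((layer$nb - 1L) * b + 1L):(layer$nb * b), , , , drop = FALSE]
  dgi <- chan_weight_grad(gsl, c(b, d[2], d[3], d[4]))
  dg <- nn_backward(layer$brg, dgi)
  dx + gap_backward(dg, d)
}

#' @export
nn_params.aspp_std <- function(layer) {
  c(nn_params(layer$br1), unlist(lapply(layer$brd, nn_params), recursive = FALSE),
    nn_params(layer$brg), nn_params(layer$fuse))
}

#' @export
nn_children.aspp_std <- function(layer) {
  c(list(layer$br1), layer$brd, list(layer$brg, layer$fuse))
}

#' Lightweight atrous spatial pyramid pooling block
#'
#' Three parallel branches: a 1x1 convolution and one depthwise-separable 3x3
#' atrous convolution per dilation rate, concatenated and fused by a 1x1
#' convolution. Strictly fewer multiply-accumulates than the standard form at
#' equal channel widths.
#'
#' @param spec a [module_spec()] whose variant uses the lightweight form.
#' @export
aspp_lightweight <- function(spec) {
  if (!spec$variant %in% c("LASPP", "LLAAM", "LAAM"))
    stop("aspp_lightweight: spec variant must be LASPP, LLAAM or LAAM")
  if (length(spec$dilation_rates) < 2L)
    stop("aspp_lightweight: at least 2 dilation rates required")
  c1 <- spec$in_channels
  b <- max(1L, as.integer(round(c1 * spec$branch_width_ratio)))
  dil_branches <- lapply(spec$dilation_rates, function(r)
    ds_conv(c1, b, 3L, dilation = r))
  nb <- 1L + length(dil_branches)
  new_layer("aspp_light", b = b, nb = nb,
            br1 = conv_block(c1, b, 1L),
            brd = dil_branches,
            fuse = conv_block(nb * b, spec$out_channels, 1L))
}

#' @export
nn_forward.aspp_light <- function(layer, x, train = FALSE) {
  d <- dim(x)
  b <- layer$b
  cat_x <- array(0, dim = c(layer$nb * b, d[2], d[3], d[4]))
  cat_x[1:b, , , ] <- nn_forward(layer$br1, x, train)
  for (i in seq_along(layer$brd))
    cat_x[(i * b + 1L):((i + 1L) * b), , , ] <-
      nn_forward(layer$brd[[i]], x, train)
  if (train) layer$in_dim <- d
  nn_forward(layer$fuse, as_fm(cat_x), train)
}

#' @export
nn_backward.aspp_light <- function(layer, dy) {
  b <- layer$b
  dcat <- nn_backward(layer$fuse, dy)
  dx <- nn_backward(layer$br1, dcat[1:b, , , , drop = FALSE])
  for (i in seq_along(layer$brd))
    dx <- dx + nn_backward(layer$brd[[i]],
                           dcat[(i * b + 1L):((i + 1L) * b), , , , drop = FALSE])
  dx
}

#' @export
nn_params.aspp_light <- function(layer) {
  c(nn_params(layer$br1), unlist(lapply(layer$brd, nn_params), recursive = FALSE),
    nn_params(layer$fuse))
}

#' @export
nn_children.aspp_light <- function(layer) {
  c(list(layer$br1), layer$brd, list(layer$fuse))
}

## ---- SPP baseline ----------------------------------------------------------

#' Classic spatial pyramid pooling block (parallel 5/9/13 max pools)
#' @param in_c,out_c channel widths.
#' @export
spp_block <- function(in_c, out_c) {
  ch <- in_c %/% 2L
  new_layer("spp_block", ch = ch,
            cv1 = conv_block(in_c, ch, 1L),
            pools = list(maxpool_same(5L), maxpool_same(9L), maxpool_same(13L)),
            cv2 = conv_block(ch * 4L, out_c, 1L))
}

#' @export
nn_forward.spp_block <- function(layer, x, train = FALSE) {
  x1 <- nn_forward(layer$cv1, x, train)
  d <- dim(x1)
  ch <- layer$ch
  cat_x <- array(0, dim = c(ch * 4L, d[2], d[3], d[4]))
  cat_x[1:ch, , , ] <- x1
  for (i in 1:3)
    cat_x[(i * ch + 1L):((i + 1L) * ch), , , ] <-
      nn_forward(layer$pools[[i]], x1, train)
  nn_forward(layer$cv2, as_fm(cat_x), train)
}

#' @export
nn_backward.spp_block <- function(layer, dy) {
  ch <- layer$ch
  dcat <- nn_backward(layer$cv2, dy)
  dx1 <- dcat[1:ch, , , , drop = FALSE]
  for (i in 1:3)
    dx1 <- dx1 + nn_backward(layer$pools[[i]],
                             dcat[(i * ch + 1L):((i + 1L) * ch), , , , drop = FALSE])
  nn_backward(layer$cv1, dx1)
}

#' @export
nn_params.spp_block <- function(layer) c(nn_params(layer$cv1), nn_params(layer$cv2))

#' @export
nn_children.spp_block <- function(layer) c(list(layer$cv1), layer$pools, list(layer$cv2))

## ---- tail variants ---------------------------------------------------------

#' Build a backbone-tail module variant by name or spec
#'
#' Returns the composed transform for the named variant of the ablation grid.
#' `SPP` is the original fixed-kernel max-pool pyramid used for baseline
#' parity. After a training-mode forward, the pre-residual activation is kept
#' in `$pre_residual`, which makes the ablation identities (variant minus
#' residual) directly observable.
#'
#' @param spec a [module_spec()] or a variant name (then `in_channels` must
#'   be given).
#' @param in_channels,out_channels used when `spec` is a name.
#' @param ... passed to [module_spec()] when `spec` is a name.
#' @export
build_variant <- function(spec, in_channels = NULL,
                          out_channels = in_channels, ...) {
  if (is.character(spec)) {
    if (!spec %in% VARIANT_NAMES)
      stop("build_variant: unknown variant '", spec, "'; valid names: ",
           paste(VARIANT_NAMES, collapse = ", "))
    stopifnot(!is.null(in_channels))
    spec <- module_spec(spec, in_channels, out_channels, ...)
  }
  comp <- variant_composition(spec$variant)
  if (spec$variant == "SPP")
    return(new_layer("tail_variant", spec = spec, kind = "SPP",
                     aspp = spp_block(spec$in_channels, spec$out_channels),
                     attn = NULL, proj = NULL))
  if (comp$residual == "identity" && spec$in_channels != spec$out_channels)
    stop("build_variant: ", spec$variant,
         " needs in_channels == out_channels for its identity residual")
  aspp <- if (comp$aspp == "standard") aspp_standard(spec) else aspp_lightweight(spec)
  attn <- switch(comp$attention,
                 none = NULL,
                 standard_cbam = cbam_standard(spec$out_channels,
                                               spec$channel_reduction),
                 simplified_cbam = cbam_enhanced(spec$out_channels,
                                                 spec$channel_reduction,
                                                 spec$dilation_rates,
                                                 spec$spatial_attention_input))
  proj <- if (comp$residual == "projected_sum")
    nn_sequential(conv2d(spec$in_channels, spec$out_channels, 1L, bias = FALSE),
                  batchnorm2d(spec$out_channels))
  else NULL
  new_layer("tail_variant", spec = spec, kind = spec$variant,
            residual = comp$residual, aspp = aspp, attn = attn, proj = proj)
}

#' @export
nn_forward.tail_variant <- function(layer, x, train = FALSE) {
  y <- nn_forward(layer$aspp, x, train)
  a <- if (is.null(layer$attn)) y else nn_forward(layer$attn, y, train)
  layer$pre_residual <- a
  out <- a
  if (identical(layer$residual, "identity")) out <- a + x
  if (identical(layer$residual, "projected_sum"))
    out <- a + nn_forward(layer$proj, x, train)
  as_fm(out)
}

#' @export
nn_backward.tail_variant <- function(layer, dy) {
  da <- dy
  dx_res <- 0
  if (identical(layer$residual, "identity")) dx_res <- dy
  if (identical(layer$residual, "projected_sum"))
    dx_res <- nn_backward(layer$proj, dy)
  if (!is.null(layer$attn)) da <- nn_backward(layer$attn, da)
  nn_backward(layer$aspp, da) + dx_res
}

#' @export
nn_params.tail_variant <- function(layer) {
  c(nn_params(layer$aspp),
    if (!is.null(layer$attn)) nn_params(layer$attn),
    if (!is.null(layer$proj)) nn_params(layer$proj))
}

#' @export
nn_children.tail_variant <- function(layer) {
  Filter(Negate(is.null), list(layer$aspp, layer$attn, layer$proj))
}
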