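# Analytic complexity profiler. Shapes are propagated symbolically through
# the module tree: no forward pass is executed, so profiling the full network
# at 640x640 costs milliseconds. The counting convention (frozen in
# gflops_convention()) follows the widespread detection-model practice:
# multiply-accumulates of convolution and fully connected layers, GFLOPs =
# 2 * MACs / 1e9, normalization/activation/pooling excluded.

#' Closed-form multiply-accumulate count of a 2-D convolution
#'
#' `out_h * out_w * out_c * (in_c / groups) * kernel^2`.
#'
#' @param in_c,out_c channel counts.
#' @param kernel kernel size.
#' @param out_h,out_w output spatial extent.
#' @param groups convolution groups (must divide both channel counts).
#' @return MAC count (numeric scalar).
#' @export
count_conv_macs <- function(in_c, out_c, kernel, out_h, out_w, groups = 1L) {
  stopifnot(in_c > 0, out_c > 0, kernel > 0, out_h >= 0, out_w >= 0)
  if (in_c %% groups != 0L || out_c %% groups != 0L)
    stop("count_conv_macs: groups must divide both channel counts")
  out_h * out_w * out_c * (in_c / groups) * kernel^2
}

prow <- function(name, params, macs) {
  data.frame(layer = name, params = params, macs = macs,
             stringsAsFactors = FALSE)
}

#' Symbolic shape/complexity propagation through a layer
#'
#' @param layer layer object.
#' @param in_shape input shape `c(channels, height, width)`.
#' @param name label used in the per-layer table.
#' @param convention counting convention, see [gflops_convention()].
#' @return list with `out_shape` and a per-layer data frame `rows`.
#' @export
nn_profile <- function(layer, in_shape, name = class(layer)[1],
                       convention = gflops_convention()) {
  UseMethod("nn_profile")
}

#' @export
nn_profile.conv2d <- function(layer, in_shape, name = class(layer)[1],
                              convention = gflops_convention()) {
  stopifnot(in_shape[1] == layer$in_c)
  oh <- (in_shape[2] + 2 * layer$pad - layer$dil * (layer$k - 1) - 1) %/%
    layer$stride + 1
  ow <- (in_shape[3] + 2 * layer$pad - layer$dil * (layer$k - 1) - 1) %/%
    layer$stride + 1
  macs <- count_conv_macs(layer$in_c, layer$out_c, layer$k, oh, ow,
                          layer$groups)
  params <- length(layer$W$value) + if (is.null(layer$b)) 0 else layer$out_c
  list(out_shape = c(layer$out_c, oh, ow), rows = prow(name, params, macs))
}

#' @export
nn_profile.batchnorm2d <- function(layer, in_shape, name = class(layer)[1],
                                   convention = gflops_convention()) {
  macs <- if (isTRUE(convention$include_elementwise))
    2 * prod(in_shape) else 0
  list(out_shape = in_shape, rows = prow(name, 2 * layer$nch, macs))
}

#' @export
nn_profile.act_silu <- function(layer, in_shape, name = class(layer)[1],
                                convention = gflops_convention()) {
  macs <- if (isTRUE(convention$include_elementwise)) prod(in_shape) else 0
  list(out_shape = in_shape, rows = prow(name, 0, macs))
}

#' @export
nn_profile.act_relu <- nn_profile.act_silu

#' @export
nn_profile.maxpool_same <- function(layer, in_shape, name = class(layer)[1],
                                    convention = gflops_convention()) {
  macs <- if (isTRUE(convention$include_elementwise))
    prod(in_shape) * layer$k^2 else 0
  list(out_shape = in_shape, rows = prow(name, 0, macs))
}

#' @export
nn_profile.upsample2x <- function(layer, in_shape, name = class(layer)[1],
                                  convention = gflops_convention()) {
  list(out_shape = c(in_shape[1], in_shape[2] * 2, in_shape[3] * 2),
       rows = prow(name, 0, 0))
}

#' @export
nn_profile.nn_sequential <- function(layer, in_shape, name = class(layer)[1],
                                     convention = gflops_convention()) {
  rows <- list()
  sh <- in_shape
  for (i in seq_along(layer$layers)) {
    sub <- nn_profile(layer$layers[[i]], sh,
                      paste0(name, ".", i, ":", class(layer$layers[[i]])[1]),
                      convention)
    sh <- sub$out_shape
    rows[[i]] <- sub$rows
  }
  list(out_shape = sh, rows = do.call(rbind, rows))
}

#' @export
nn_profile.chan_attn <- function(layer, in_shape, name = class(layer)[1],
                                 convention = gflops_convention()) {
  c <- layer$nch; h <- layer$hidden
  macs <- c * h + h * c          # two 1x1-extent linear maps
  params <- length(layer$W1$value) + length(layer$W2$value) +
    (if (is.null(layer$b1)) 0 else h) + (if (is.null(layer$b2)) 0 else c)
  list(out_shape = c(c, 1, 1), rows = prow(name, params, macs))
}

#' @export
nn_profile.spat_attn <- function(layer, in_shape, name = class(layer)[1],
                                 convention = gflops_convention()) {
  conv_in <- if (layer$pooled) c(2, in_shape[2], in_shape[3]) else in_shape
  sub <- nn_profile(layer$conv, conv_in, paste0(name, ".conv"), convention)
  list(out_shape = c(1, in_shape[2], in_shape[3]), rows = sub$rows)
}

#' @export
nn_profile.attn_cbam <- function(layer, in_shape, name = class(layer)[1],
                                 convention = gflops_convention()) {
  r1 <- nn_profile(layer$chan, in_shape, paste0(name, ".chan"), convention)
  r2 <- nn_profile(layer$spat, in_shape, paste0(name, ".spat"), convention)
  list(out_shape = in_shape, rows = rbind(r1$rows, r2$rows))
}

#' @export
nn_profile.attn_enhanced <- function(layer, in_shape, name = class(layer)[1],
                                     convention = gflops_convention()) {
  r0 <- nn_profile(layer$ctx1, in_shape, paste0(name, ".ctx1"), convention)
  r0b <- nn_profile(layer$ctx2, in_shape, paste0(name, ".ctx2"), convention)
  r1 <- nn_profile(layer$chan, in_shape, paste0(name, ".chan"), convention)
  r2 <- nn_profile(layer$spat, in_shape, paste0(name, ".spat"), convention)
  list(out_shape = in_shape, rows = rbind(r0$rows, r0b$rows, r1$rows, r2$rows))
}

#' @export
nn_profile.aspp_std <- function(layer, in_shape, name = class(layer)[1],
                                convention = gflops_convention()) {
  rows <- list(nn_profile(layer$br1, in_shape, paste0(name, ".br1"),
                          convention)$rows)
  for (i in seq_along(layer$brd))
    rows[[length(rows) + 1L]] <-
      nn_profile(layer$brd[[i]], in_shape, paste0(name, ".dil", i),
                 convention)$rows
  # global-pool branch convolves a 1x1 extent
  rows[[length(rows) + 1L]] <-
    nn_profile(layer$brg, c(in_shape[1], 1, 1), paste0(name, ".gap"),
               convention)$rows
  fuse_in <- c(layer$nb * layer$b, in_shape[2], in_shape[3])
  fuse <- nn_profile(layer$fuse, fuse_in, paste0(name, ".fuse"), convention)
  rows[[length(rows) + 1L]] <- fuse$rows
  list(out_shape = fuse$out_shape, rows = do.call(rbind, rows))
}

#' @export
nn_profile.aspp_light <- function(layer, in_shape, name = class(layer)[1],
                                  convention = gflops_convention()) {
  rows <- list(nn_profile(layer$br1, in_shape, paste0(name, ".br1"),
                          convention)$rows)
  for (i in seq_along(layer$brd))
    rows[[length(rows) + 1L]] <-
      nn_profile(layer$brd[[i]], in_shape, paste0(name, ".ds", i),
                 convention)$rows
  fuse_in <- c(layer$nb * layer$b, in_shape[2], in_shape[3])
  fuse <- nn_profile(layer$fuse, fuse_in, paste0(name, ".fuse"), convention)
  rows[[length(rows) + 1L]] <- fuse$rows
  list(out_shape = fuse$out_shape, rows = do.call(rbind, rows))
}

#' @export
nn_profile.spp_block <- function(layer, in_shape, name = class(layer)[1],
                                 convention = gflops_convention()) {
  r1 <- nn_profile(layer$cv1, in_shape, paste0(name, ".cv1"), convention)
  rows <- list(r1$rows)
  for (i in 1:3)
    rows[[length(rows) + 1L]] <-
      nn_profile(layer$pools[[i]], r1$out_shape,
                 paste0(name, ".pool", i), convention)$rows
  cv2 <- nn_profile(layer$cv2, c(layer$ch * 4, in_shape[2], in_shape[3]),
                    paste0(name, ".cv2"), convention)
  rows[[length(rows) + 1L]] <- cv2$rows
  list(out_shape = cv2$out_shape, rows = do.call(rbind, rows))
}

#' @export
nn_profile.tail_variant <- function(layer, in_shape, name = layer$kind,
                                    convention = gflops_convention()) {
  r1 <- nn_profile(layer$aspp, in_shape, paste0(name, ".aspp"), convention)
  rows <- list(r1$rows)
  if (!is.null(layer$attn))
    rows[[length(rows) + 1L]] <-
      nn_profile(layer$attn, r1$out_shape, paste0(name, ".attn"),
                 convention)$rows
  if (!is.null(layer$proj))
    rows[[length(rows) + 1L]] <-
      nn_profile(layer$proj, in_shape, paste0(name, ".residual"),
                 convention)$rows
  list(out_shape = r1$out_shape, rows = do.call(rbind, rows))
}

#' Profile a module or model: parameters, MACs and GFLOPs
#'
#' Traverses the layer tree symbolically, sums parameters and analytic
#' multiply-accumulate counts, and converts MACs to GFLOPs under the stated
#' convention.
#'
#' @param x layer, tail module or `seg_model`.
#' @param input_shape input `c(channels, height, width)`; for a `seg_model`
#'   defaults to its configured input size.
#' @param convention see [gflops_convention()].
#' @return a `complexity_report`: list with `params`, `macs`, `gflops`,
#'   `per_layer` data frame.
#' @export
profile_network <- function(x, input_shape = NULL,
                            convention = gflops_convention()) {
  if (inherits(x, "seg_model")) {
    if (is.null(input_shape))
      input_shape <- c(3, x$cfg$input_size[1], x$cfg$input_size[2])
    pr <- profile_seg_model(x, input_shape, convention)
  } else {
    stopifnot(!is.null(input_shape))
    pr <- nn_profile(x, input_shape, convention = convention)
  }
  rows <- pr$rows
  rep <- list(params = sum(rows$params), macs = sum(rows$macs),
              gflops = convention$flops_per_mac * sum(rows$macs) / 1e9,
              per_layer = rows, input_shape = input_shape)
  class(rep) <- "complexity_report"
  rep
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity report @ input (%s)\n",
              paste(x$input_shape, collapse = "x")))
  cat(sprintf("  params: %s\n", format(x$params, big.mark = ",")))
  cat(sprintf("  MACs:   %s\n", format(x$macs, big.mark = ",")))
  cat(sprintf("  GFLOPs: %.1f\n", x$gflops))
  invisible(x)
}
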