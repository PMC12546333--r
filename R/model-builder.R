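# YOLOv5s-style instance-segmentation network: CSP (C3) backbone, PANet neck,
# anchor-based detection head with prototype-mask segmentation branch. The
# backbone-tail slot (between the last C3 stage and the neck) accepts any
# variant from the tail-module registry; its input/output widths equal the
# original slot widths so the neck wiring is untouched by a swap.

make_div8 <- function(x) as.integer(max(8, round(x / 8) * 8))

#' Model configuration
#'
#' @param input_size input `(height, width)` in pixels, divisible by 32.
#' @param num_classes number of object classes.
#' @param tail_variant variant name (see [VARIANT_NAMES]) or a
#'   [module_spec()]; channel widths are filled in from the architecture.
#' @param depth_multiple,width_multiple YOLOv5s compound-scaling factors.
#' @param seed RNG seed controlling weight initialization.
#' @param ... extra [module_spec()] arguments when `tail_variant` is a name.
#' @return a `model_config` list.
#' @export
model_config <- function(input_size = c(640, 640), num_classes = 2,
                         tail_variant = "SPP", depth_multiple = 0.33,
                         width_multiple = 0.50, seed = 0L, ...) {
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  if (any(input_size %% 32 != 0))
    stop("model_config: input_size must be divisible by 32")
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 tail_variant = tail_variant,
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 seed = as.integer(seed),
                 tail_args = list(...)),
            class = "model_config")
}

## ---- focus (space-to-depth stem) -------------------------------------------

focus_layer <- function(out_c) {
  new_layer("focus_layer", conv = conv_block(12L, out_c, 3L))
}

space_to_depth <- function(x) {
  d <- dim(x)
  oy <- seq(1L, d[2], by = 2L); ey <- seq(2L, d[2], by = 2L)
  ox <- seq(1L, d[3], by = 2L); ex <- seq(2L, d[3], by = 2L)
  out <- array(0, dim = c(4L * d[1], d[2] %/% 2L, d[3] %/% 2L, d[4]))
  out[1:d[1], , , ] <- x[, oy, ox, , drop = FALSE]
  out[(d[1] + 1):(2 * d[1]), , , ] <- x[, ey, ox, , drop = FALSE]
  out[(2 * d[1] + 1):(3 * d[1]), , , ] <- x[, oy, ex, , drop = FALSE]
  out[(3 * d[1] + 1):(4 * d[1]), , , ] <- x[, ey, ex, , drop = FALSE]
  out
}

#' @export
nn_forward.focus_layer <- function(layer, x, train = FALSE) {
  if (train) layer$in_dim <- dim(x)
  nn_forward(layer$conv, as_fm(space_to_depth(x)), train)
}

#' @export
nn_backward.focus_layer <- function(layer, dy) {
  dsd <- nn_backward(layer$conv, dy)
  d <- layer$in_dim
  dx <- array(0, dim = d)
  oy <- seq(1L, d[2], by = 2L); ey <- seq(2L, d[2], by = 2L)
  ox <- seq(1L, d[3], by = 2L); ex <- seq(2L, d[3], by = 2L)
  c1 <- d[1]
  dx[, oy, ox, ] <- dsd[1:c1, , , ]
  dx[, ey, ox, ] <- dsd[(c1 + 1):(2 * c1), , , ]
  dx[, oy, ex, ] <- dsd[(2 * c1 + 1):(3 * c1), , , ]
  dx[, ey, ex, ] <- dsd[(3 * c1 + 1):(4 * c1), , , ]
  dx
}

#' @export
nn_params.focus_layer <- function(layer) nn_params(layer$conv)

#' @export
nn_children.focus_layer <- function(layer) list(layer$conv)

#' @export
nn_profile.focus_layer <- function(layer, in_shape, name = "focus",
                                   convention = gflops_convention()) {
  nn_profile(layer$conv, c(4 * in_shape[1], in_shape[2] %/% 2,
                           in_shape[3] %/% 2), name, convention)
}

## ---- C3 / bottleneck -------------------------------------------------------

bottleneck_block <- function(c, shortcut = TRUE) {
  new_layer("bottleneck_block", shortcut = shortcut,
            cv1 = conv_block(c, c, 1L), cv2 = conv_block(c, c, 3L))
}

#' @export
nn_forward.bottleneck_block <- function(layer, x, train = FALSE) {
  y <- nn_forward(layer$cv2, nn_forward(layer$cv1, x, train), train)
  if (layer$shortcut) y <- y + x
  as_fm(y)
}

#' @export
nn_backward.bottleneck_block <- function(layer, dy) {
  dx <- nn_backward(layer$cv1, nn_backward(layer$cv2, dy))
  if (layer$shortcut) dx <- dx + dy
  dx
}

#' @export
nn_params.bottleneck_block <- function(layer) c(nn_params(layer$cv1), nn_params(layer$cv2))

#' @export
nn_children.bottleneck_block <- function(layer) list(layer$cv1, layer$cv2)

#' @export
nn_profile.bottleneck_block <- function(layer, in_shape, name = "bneck",
                                        convention = gflops_convention()) {
  r1 <- nn_profile(layer$cv1, in_shape, paste0(name, ".cv1"), convention)
  r2 <- nn_profile(layer$cv2, r1$out_shape, paste0(name, ".cv2"), convention)
  list(out_shape = r2$out_shape, rows = rbind(r1$rows, r2$rows))
}

c3_block <- function(c1, c2, n = 1L, shortcut = TRUE) {
  ch <- c2 %/% 2L
  new_layer("c3_block", ch = ch,
            cv1 = conv_block(c1, ch, 1L),
            cv2 = conv_block(c1, ch, 1L),
            m = lapply(seq_len(n), function(i) bottleneck_block(ch, shortcut)),
            cv3 = conv_block(2L * ch, c2, 1L))
}

#' @export
nn_forward.c3_block <- function(layer, x, train = FALSE) {
  a <- nn_forward(layer$cv1, x, train)
  for (bl in layer$m) a <- nn_forward(bl, a, train)
  b <- nn_forward(layer$cv2, x, train)
  d <- dim(a)
  ch <- layer$ch
  cat_x <- array(0, dim = c(2L * ch, d[2], d[3], d[4]))
  cat_x[1:ch, , , ] <- a
  cat_x[(ch + 1L):(2L * ch), , , ] <- b
  nn_forward(layer$cv3, as_fm(cat_x), train)
}

#' @export
nn_backward.c3_block <- function(layer, dy) {
  ch <- layer$ch
  dcat <- nn_backward(layer$cv3, dy)
  da <- dcat[1:ch, , , , drop = FALSE]
  db <- dcat[(ch + 1L):(2L * ch), , , , drop = FALSE]
  for (bl in rev(layer$m)) da <- nn_backward(bl, da)
  nn_backward(layer$cv1, da) + nn_backward(layer$cv2, db)
}

#' @export
nn_params.c3_block <- function(layer) {
  c(nn_params(layer$cv1), nn_params(layer$cv2),
    unlist(lapply(layer$m, nn_params), recursive = FALSE),
    nn_params(layer$cv3))
}

#' @export
nn_children.c3_block <- function(layer) {
  c(list(layer$cv1, layer$cv2), layer$m, list(layer$cv3))
}

#' @export
nn_profile.c3_block <- function(layer, in_shape, name = "C3",
                                convention = gflops_convention()) {
  r1 <- nn_profile(layer$cv1, in_shape, paste0(name, ".cv1"), convention)
  rows <- list(r1$rows)
  sh <- r1$out_shape
  for (i in seq_along(layer$m)) {
    rb <- nn_profile(layer$m[[i]], sh, paste0(name, ".m", i), convention)
    rows[[length(rows) + 1L]] <- rb$rows
    sh <- rb$out_shape
  }
  rows[[length(rows) + 1L]] <-
    nn_profile(layer$cv2, in_shape, paste0(name, ".cv2"), convention)$rows
  cv3 <- nn_profile(layer$cv3, c(2 * layer$ch, in_shape[2], in_shape[3]),
                    paste0(name, ".cv3"), convention)
  rows[[length(rows) + 1L]] <- cv3$rows
  list(out_shape = cv3$out_shape, rows = do.call(rbind, rows))
}

## ---- model assembly --------------------------------------------------------

default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

#' Build the segmentation network
#'
#' Assembles the backbone, tail slot, neck and head under the given
#' configuration. Weight initialization is fully determined by `cfg$seed`.
#'
#' @param cfg a [model_config()].
#' @return a `seg_model` object.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  w <- cfg$width_multiple; dm <- cfg$depth_multiple
  ch <- vapply(c(64, 128, 256, 512, 1024), function(c) make_div8(c * w),
               integer(1))
  c0 <- ch[1]; c1 <- ch[2]; c2 <- ch[3]; c3 <- ch[4]; c4 <- ch[5]
  nd <- function(n) max(1L, as.integer(round(n * dm)))
  tail_spec <- cfg$tail_variant
  if (is.character(tail_spec))
    tail_spec <- do.call(module_spec,
                         c(list(variant = tail_spec, in_channels = c4,
                                out_channels = c4), cfg$tail_args))
  if (tail_spec$in_channels != c4 || tail_spec$out_channels != c4)
    stop("build_model: tail slot widths must equal the original slot (",
         c4, " channels)")
  nc <- cfg$num_classes; nm <- 32L; na <- 3L
  no <- na * (5L + nc + nm)
  m <- new_layer("seg_model",
    cfg = cfg, nc = nc, nm = nm, na = na, no = no,
    strides = c(8L, 16L, 32L), anchors = default_anchors(),
    chs = c(c0, c1, c2, c3, c4),
    L0 = focus_layer(c0),
    L1 = conv_block(c0, c1, 3L, stride = 2L),
    L2 = c3_block(c1, c1, nd(3)),
    L3 = conv_block(c1, c2, 3L, stride = 2L),
    L4 = c3_block(c2, c2, nd(6)),
    L5 = conv_block(c2, c3, 3L, stride = 2L),
    L6 = c3_block(c3, c3, nd(9)),
    L7 = conv_block(c3, c4, 3L, stride = 2L),
    L8 = c3_block(c4, c4, nd(3)),
    tail = build_variant(tail_spec),
    L10 = conv_block(c4, c3, 1L),
    L11 = upsample2x(),
    L13 = c3_block(2L * c3, c3, nd(3), shortcut = FALSE),
    L14 = conv_block(c3, c2, 1L),
    L15 = upsample2x(),
    L17 = c3_block(2L * c2, c2, nd(3), shortcut = FALSE),
    L18 = conv_block(c2, c2, 3L, stride = 2L),
    L20 = c3_block(2L * c2, c3, nd(3), shortcut = FALSE),
    L21 = conv_block(c3, c3, 3L, stride = 2L),
    L23 = c3_block(2L * c3, c4, nd(3), shortcut = FALSE),
    proto_cv1 = conv_block(c2, c2, 3L),
    proto_up = upsample2x(),
    proto_cv2 = conv_block(c2, c2, 3L),
    proto_cv3 = conv_block(c2, nm, 1L),
    det3 = conv2d(c2, no, 1L, bias = TRUE),
    det4 = conv2d(c3, no, 1L, bias = TRUE),
    det5 = conv2d(c4, no, 1L, bias = TRUE))
  init_detect_bias(m)
  m
}

# objectness/class bias priors (stabilize early training, YOLO convention);
# a fixed 1% objectness prior behaves sensibly at any grid size, where the
# objects-per-cell heuristic degenerates for coarse grids
init_detect_bias <- function(m) {
  npc <- 5L + m$nc + m$nm
  for (i in 1:3) {
    det <- m[[c("det3", "det4", "det5")[i]]]
    b <- det$b$value
    for (a in seq_len(m$na)) {
      off <- (a - 1L) * npc
      b[off + 5L] <- log(0.01 / 0.99)
      b[off + 5L + seq_len(m$nc)] <- log(0.6 / (m$nc - 0.99))
    }
    det$b$value <- b
  }
  invisible(m)
}

model_layer_names <- function() {
  c("L0", "L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8", "tail",
    "L10", "L13", "L14", "L17", "L18", "L20", "L21", "L23",
    "proto_cv1", "proto_cv2", "proto_cv3", "det3", "det4", "det5")
}

#' Named parameter-shape table of a model (for slot-isolation diffs)
#' @param m a `seg_model`.
#' @return data.frame with layer name, parameter index and dimensions.
#' @export
param_shapes <- function(m) {
  rows <- list()
  for (nm in model_layer_names()) {
    ps <- nn_params(m[[nm]])
    for (i in seq_along(ps))
      rows[[length(rows) + 1L]] <-
        data.frame(layer = nm, idx = i,
                   shape = paste(dim(ps[[i]]$value) %||%
                                   length(ps[[i]]$value), collapse = "x"),
                   stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
nn_params.seg_model <- function(layer) {
  unlist(lapply(model_layer_names(), function(nm) nn_params(layer[[nm]])),
         recursive = FALSE)
}

#' @export
nn_children.seg_model <- function(layer) {
  lapply(model_layer_names(), function(nm) layer[[nm]])
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[1:da[1], , , ] <- a
  out[(da[1] + 1):(da[1] + db[1]), , , ] <- b
  as_fm(out)
}

#' Raw network forward pass
#'
#' @param m a `seg_model`.
#' @param x input images, dim (3, H, W, B), values in \[0, 1\].
#' @param train training mode.
#' @return list with raw head outputs `p3`, `p4`, `p5` (each
#'   `(no, gy, gx, B)`), mask prototypes `proto` `(nm, H/4, W/4, B)` and the
#'   tail activation `tail_out`.
#' @export
seg_forward <- function(m, x, train = FALSE) {
  x0 <- nn_forward(m$L0, x, train)
  x1 <- nn_forward(m$L1, x0, train)
  x2 <- nn_forward(m$L2, x1, train)
  x3 <- nn_forward(m$L3, x2, train)
  x4 <- nn_forward(m$L4, x3, train)
  x5 <- nn_forward(m$L5, x4, train)
  x6 <- nn_forward(m$L6, x5, train)
  x7 <- nn_forward(m$L7, x6, train)
  x8 <- nn_forward(m$L8, x7, train)
  x9 <- nn_forward(m$tail, x8, train)
  x10 <- nn_forward(m$L10, x9, train)
  x11 <- nn_forward(m$L11, x10, train)
  x13 <- nn_forward(m$L13, cat_channels(x11, x6), train)
  x14 <- nn_forward(m$L14, x13, train)
  x15 <- nn_forward(m$L15, x14, train)
  x17 <- nn_forward(m$L17, cat_channels(x15, x4), train)
  x18 <- nn_forward(m$L18, x17, train)
  x20 <- nn_forward(m$L20, cat_channels(x18, x14), train)
  x21 <- nn_forward(m$L21, x20, train)
  x23 <- nn_forward(m$L23, cat_channels(x21, x10), train)
  proto <- nn_forward(m$proto_cv3,
                      nn_forward(m$proto_cv2,
                                 nn_forward(m$proto_up,
                                            nn_forward(m$proto_cv1, x17, train),
                                            train), train), train)
  out <- list(p3 = nn_forward(m$det3, x17, train),
              p4 = nn_forward(m$det4, x20, train),
              p5 = nn_forward(m$det5, x23, train),
              proto = proto, tail_out = x9)
  if (train) m$ch_split <- list(c10 = dim(x10)[1], c14 = dim(x14)[1],
                                c6 = dim(x6)[1], c4 = dim(x4)[1],
                                c18 = dim(x18)[1], c21 = dim(x21)[1],
                                c15 = dim(x15)[1], c11 = dim(x11)[1])
  out
}

#' Backward pass from head gradients to the input
#'
#' Must follow a training-mode [seg_forward()]. Parameter gradients are
#' accumulated in place; the gradient reaching the tail-module output is kept
#' in `m$grad_tail_out` (used by Grad-CAM).
#'
#' @param m a `seg_model`.
#' @param grads list with `p3`, `p4`, `p5`, `proto` gradient arrays.
#' @return gradient w.r.t. the input batch.
#' @export
seg_backward <- function(m, grads) {
  cs <- m$ch_split
  d17 <- nn_backward(m$det3, grads$p3)
  dproto <- nn_backward(m$proto_cv1,
                        nn_backward(m$proto_up,
                                    nn_backward(m$proto_cv2,
                                                nn_backward(m$proto_cv3,
                                                            grads$proto))))
  d17 <- d17 + dproto
  d20 <- nn_backward(m$det4, grads$p4)
  d23 <- nn_backward(m$det5, grads$p5)
  d22 <- nn_backward(m$L23, d23)
  d21 <- d22[1:cs$c21, , , , drop = FALSE]
  d10 <- d22[(cs$c21 + 1):(cs$c21 + cs$c10), , , , drop = FALSE]
  d20 <- d20 + nn_backward(m$L21, d21)
  d19 <- nn_backward(m$L20, d20)
  d18 <- d19[1:cs$c18, , , , drop = FALSE]
  d14 <- d19[(cs$c18 + 1):(cs$c18 + cs$c14), , , , drop = FALSE]
  d17 <- d17 + nn_backward(m$L18, d18)
  d16 <- nn_backward(m$L17, d17)
  d15 <- d16[1:cs$c15, , , , drop = FALSE]
  d4 <- d16[(cs$c15 + 1):(cs$c15 + cs$c4), , , , drop = FALSE]
  d14 <- d14 + nn_backward(m$L15, d15)
  d13 <- nn_backward(m$L14, d14)
  d12 <- nn_backward(m$L13, d13)
  d11 <- d12[1:cs$c11, , , , drop = FALSE]
  d6 <- d12[(cs$c11 + 1):(cs$c11 + cs$c6), , , , drop = FALSE]
  d10 <- d10 + nn_backward(m$L11, d11)
  d9 <- nn_backward(m$L10, d10)
  m$grad_tail_out <- d9
  d8 <- nn_backward(m$tail, d9)
  d7 <- nn_backward(m$L8, d8)
  d6 <- d6 + nn_backward(m$L7, d7)
  d5 <- nn_backward(m$L6, d6)
  d4 <- d4 + nn_backward(m$L5, d5)
  d3 <- nn_backward(m$L4, d4)
  d2 <- nn_backward(m$L3, d3)
  d1 <- nn_backward(m$L2, d2)
  d0 <- nn_backward(m$L1, d1)
  nn_backward(m$L0, d0)
}

profile_seg_model <- function(m, in_shape, convention = gflops_convention()) {
  rows <- list()
  pr <- function(layer, sh, nm) {
    r <- nn_profile(layer, sh, nm, convention)
    rows[[length(rows) + 1L]] <<- r$rows
    r$out_shape
  }
  s0 <- pr(m$L0, in_shape, "stem")
  s1 <- pr(m$L1, s0, "down1")
  s2 <- pr(m$L2, s1, "C3_2")
  s3 <- pr(m$L3, s2, "down2")
  s4 <- pr(m$L4, s3, "C3_4")
  s5 <- pr(m$L5, s4, "down3")
  s6 <- pr(m$L6, s5, "C3_6")
  s7 <- pr(m$L7, s6, "down4")
  s8 <- pr(m$L8, s7, "C3_8")
  s9 <- pr(m$tail, s8, paste0("tail_", m$tail$kind))
  s10 <- pr(m$L10, s9, "neck_cv1")
  s11 <- c(s10[1], s10[2] * 2, s10[3] * 2)
  s13 <- pr(m$L13, c(s11[1] + s6[1], s11[2], s11[3]), "neck_C3_13")
  s14 <- pr(m$L14, s13, "neck_cv2")
  s15 <- c(s14[1], s14[2] * 2, s14[3] * 2)
  s17 <- pr(m$L17, c(s15[1] + s4[1], s15[2], s15[3]), "neck_C3_17")
  s18 <- pr(m$L18, s17, "neck_down1")
  s20 <- pr(m$L20, c(s18[1] + s14[1], s18[2], s18[3]), "neck_C3_20")
  s21 <- pr(m$L21, s20, "neck_down2")
  s23 <- pr(m$L23, c(s21[1] + s10[1], s21[2], s21[3]), "neck_C3_23")
  sp1 <- pr(m$proto_cv1, s17, "proto_cv1")
  sp2 <- c(sp1[1], sp1[2] * 2, sp1[3] * 2)
  sp3 <- pr(m$proto_cv2, sp2, "proto_cv2")
  pr(m$proto_cv3, sp3, "proto_cv3")
  pr(m$det3, s17, "detect_p3")
  pr(m$det4, s20, "detect_p4")
  pr(m$det5, s23, "detect_p5")
  list(out_shape = NULL, rows = do.call(rbind, rows))
}

## ---- decoding, NMS, prediction ---------------------------------------------

#' Greedy non-maximum suppression
#'
#' Keeps the highest-confidence box, removes others overlapping it with
#' IoU strictly above `iou_thr`, repeats. `iou_thr = 1` therefore suppresses
#' nothing.
#'
#' @param boxes matrix (n x 4) in `xyxy`.
#' @param scores length-n confidences.
#' @param iou_thr suppression threshold.
#' @return indices of retained boxes (in decreasing score order).
#' @export
nms_greedy <- function(boxes, scores, iou_thr = 0.45) {
  keep <- integer(0)
  ord <- order(scores, decreasing = TRUE)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1) break
    rest <- ord[-1]
    ious <- box_iou_xyxy(boxes[i, , drop = FALSE],
                         boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[ious <= iou_thr]
  }
  keep
}

#' Pairwise IoU of axis-aligned boxes in `xyxy` form
#' @param a,b matrices (na x 4), (nb x 4).
#' @return na x nb IoU matrix.
#' @export
box_iou_xyxy <- function(a, b) {
  na_ <- nrow(a); nb_ <- nrow(b)
  out <- matrix(0, na_, nb_)
  for (i in seq_len(na_)) {
    ix1 <- pmax(a[i, 1], b[, 1]); iy1 <- pmax(a[i, 2], b[, 2])
    ix2 <- pmin(a[i, 3], b[, 3]); iy2 <- pmin(a[i, 4], b[, 4])
    iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
    inter <- iw * ih
    ua <- (a[i, 3] - a[i, 1]) * (a[i, 4] - a[i, 2]) +
      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
    out[i, ] <- ifelse(ua > 0, inter / ua, 0)
  }
  out
}

decode_scale <- function(m, raw, si, bi) {
  d <- dim(raw)
  npc <- 5L + m$nc + m$nm
  gy <- d[2]; gx <- d[3]
  st <- m$strides[si]
  anch <- m$anchors[[si]]
  rows <- list()
  for (a in seq_len(m$na)) {
    off <- (a - 1L) * npc
    txy <- raw[off + 1:2, , , bi, drop = FALSE]
    twh <- raw[off + 3:4, , , bi, drop = FALSE]
    tobj <- raw[off + 5L, , , bi]
    tcls <- raw[off + 5L + seq_len(m$nc), , , bi, drop = FALSE]
    coef <- raw[off + 5L + m$nc + seq_len(m$nm), , , bi, drop = FALSE]
    cxg <- matrix(rep(0:(gx - 1), each = gy), gy, gx)
    cyg <- matrix(rep(0:(gy - 1), gx), gy, gx)
    px <- (2 * sigmoid(txy[1, , , 1]) - 0.5 + cxg) * st
    py <- (2 * sigmoid(txy[2, , , 1]) - 0.5 + cyg) * st
    pw <- (2 * sigmoid(twh[1, , , 1]))^2 * anch[a, 1]
    ph <- (2 * sigmoid(twh[2, , , 1]))^2 * anch[a, 2]
    obj <- sigmoid(tobj)
    cls <- array(sigmoid(tcls), dim = c(m$nc, gy, gx))
    best <- apply(cls, c(2, 3), which.max)
    bestp <- apply(cls, c(2, 3), max)
    conf <- obj * bestp
    rows[[a]] <- data.frame(
      conf = as.numeric(conf), class_id = as.integer(best) - 1L,
      px = as.numeric(px), py = as.numeric(py),
      pw = as.numeric(pw), ph = as.numeric(ph),
      scale = si, anchor = a,
      cell = seq_len(gy * gx))
    rows[[a]]$coef <- t(matrix(coef, nrow = m$nm))
  }
  do.call(rbind, rows)
}

#' Run inference: decode, confidence-filter, NMS, assemble masks
#'
#' @param m a `seg_model`.
#' @param images array (3, H, W, B), values normalized to \[0, 1\].
#' @param conf_thr confidence threshold.
#' @param nms_iou NMS IoU threshold.
#' @return list (length B) of `prediction_set`s: each a list with `boxes`
#'   (data.frame: class_id, conf, cx, cy, w, h in normalized units) and
#'   `masks` (list of logical H x W matrices).
#' @export
forward_predict <- function(m, images, conf_thr = 0.25, nms_iou = 0.45) {
  if (max(images) > 1 + 1e-6)
    stop("forward_predict: images must be normalized to [0,1]")
  d <- dim(images)
  out <- seg_forward(m, as_fm(images), train = FALSE)
  H <- d[2]; W <- d[3]
  res <- vector("list", d[4])
  for (bi in seq_len(d[4])) {
    cand <- rbind(decode_scale(m, out$p3, 1L, bi),
                  decode_scale(m, out$p4, 2L, bi),
                  decode_scale(m, out$p5, 3L, bi))
    cand <- cand[cand$conf > conf_thr, , drop = FALSE]
    keep_all <- integer(0)
    if (nrow(cand) > 0) {
      boxes <- cbind(cand$px - cand$pw / 2, cand$py - cand$ph / 2,
                     cand$px + cand$pw / 2, cand$py + cand$ph / 2)
      for (cl in unique(cand$class_id)) {
        sel <- which(cand$class_id == cl)
        k <- nms_greedy(boxes[sel, , drop = FALSE], cand$conf[sel], nms_iou)
        keep_all <- c(keep_all, sel[k])
      }
      keep_all <- keep_all[order(cand$conf[keep_all], decreasing = TRUE)]
    }
    kept <- cand[keep_all, , drop = FALSE]
    masks <- vector("list", nrow(kept))
    if (nrow(kept) > 0) {
      protom <- matrix(out$proto[, , , bi], nrow = m$nm)
      hp <- dim(out$proto)[2]; wp <- dim(out$proto)[3]
      for (i in seq_len(nrow(kept))) {
        logit <- matrix(as.numeric(kept$coef[i, ] %*% protom), hp, wp)
        mk <- sigmoid(logit)
        mk <- mk[rep(seq_len(hp), each = H %/% hp),
                 rep(seq_len(wp), each = W %/% wp)]
        # crop to the predicted box
        x1 <- max(1, floor(kept$px[i] - kept$pw[i] / 2))
        x2 <- min(W, ceiling(kept$px[i] + kept$pw[i] / 2))
        y1 <- max(1, floor(kept$py[i] - kept$ph[i] / 2))
        y2 <- min(H, ceiling(kept$py[i] + kept$ph[i] / 2))
        keepm <- matrix(FALSE, H, W)
        if (x2 >= x1 && y2 >= y1) keepm[y1:y2, x1:x2] <- TRUE
        masks[[i]] <- (mk > 0.5) & keepm
      }
    }
    res[[bi]] <- structure(
      list(boxes = data.frame(class_id = kept$class_id, conf = kept$conf,
                              cx = kept$px / W, cy = kept$py / H,
                              w = kept$pw / W, h = kept$ph / H),
           masks = masks),
      class = "prediction_set")
  }
  res
}
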