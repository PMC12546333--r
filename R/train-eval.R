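# Desk-scale training/evaluation harness. The composite loss follows the
# YOLOv5 segmentation recipe: (1 - IoU) box regression on decoded boxes,
# binary cross-entropy objectness with IoU-valued targets and per-scale
# balance weights, per-class BCE, and prototype-mask BCE cropped to the
# ground-truth box and normalized by its area. All gradients are derived
# analytically and pushed through seg_backward().

#' Training configuration
#'
#' @param batch_size images per SGD step.
#' @param lr0 initial learning rate (SGD).
#' @param epochs training epochs.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param eval_iou_thresholds matching thresholds reported by [evaluate()].
#' @param seed RNG seed for shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 8L, lr0 = 1e-2, epochs = 10L,
                         momentum = 0.937, weight_decay = 5e-4,
                         eval_iou_thresholds = c(0.6, 0.7, 0.8, 0.9),
                         seed = 0L) {
  stopifnot(batch_size >= 1, lr0 > 0)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 epochs = as.integer(epochs), momentum = momentum,
                 weight_decay = weight_decay,
                 eval_iou_thresholds = eval_iou_thresholds,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Distance-IoU loss pieces: IoU and the DIoU penalty (squared center
# distance over the squared enclosing-box diagonal), with analytic gradients
# w.r.t. the predicted (cx, cy, w, h) box. The distance term keeps a useful
# gradient even with little or no overlap.
box_iou_grad <- function(p, g) {
  ax1 <- p[1] - p[3] / 2; ax2 <- p[1] + p[3] / 2
  ay1 <- p[2] - p[4] / 2; ay2 <- p[2] + p[4] / 2
  bx1 <- g[1] - g[3] / 2; bx2 <- g[1] + g[3] / 2
  by1 <- g[2] - g[4] / 2; by2 <- g[2] + g[4] / 2
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  if (iw > 0 && ih > 0) {
    I <- iw * ih
    U <- p[3] * p[4] + g[3] * g[4] - I
    diw_dx <- (ax2 < bx2) - (ax1 > bx1)
    diw_dw <- 0.5 * (ax2 < bx2) + 0.5 * (ax1 > bx1)
    dih_dy <- (ay2 < by2) - (ay1 > by1)
    dih_dh <- 0.5 * (ay2 < by2) + 0.5 * (ay1 > by1)
    dI <- c(ih * diw_dx, iw * dih_dy, ih * diw_dw, iw * dih_dh)
    dA <- c(0, 0, p[4], p[3])
    iou <- I / U
    diou <- (dI * U - I * (dA - dI)) / U^2
  } else {
    iou <- 0
    diou <- c(0, 0, 0, 0)
  }
  # enclosing box and center-distance penalty
  cw <- max(ax2, bx2) - min(ax1, bx1)
  chh <- max(ay2, by2) - min(ay1, by1)
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- (p[1] - g[1])^2 + (p[2] - g[2])^2
  dc2 <- c(2 * cw * ((ax2 > bx2) - (ax1 < bx1)),
           2 * chh * ((ay2 > by2) - (ay1 < by1)),
           2 * cw * 0.5 * ((ax2 > bx2) + (ax1 < bx1)),
           2 * chh * 0.5 * ((ay2 > by2) + (ay1 < by1)))
  drho2 <- c(2 * (p[1] - g[1]), 2 * (p[2] - g[2]), 0, 0)
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  # gradient of the DIoU loss (1 - iou + rho^2/c^2)
  list(iou = iou, loss = 1 - iou + rho2 / c2, grad_loss = -diou + dpen)
}

# v5-style target assignment for one scale
assign_targets <- function(m, si, gts, input_hw) {
  st <- m$strides[si]
  gy <- input_hw[1] %/% st; gx <- input_hw[2] %/% st
  anch_g <- m$anchors[[si]] / st
  rows <- list()
  for (bi in seq_along(gts)) {
    for (ti in seq_along(gts[[bi]])) {
      lb <- gts[[bi]][[ti]]
      bxg <- lb$bbox[1] * input_hw[2] / st
      byg <- lb$bbox[2] * input_hw[1] / st
      bwg <- lb$bbox[3] * input_hw[2] / st
      bhg <- lb$bbox[4] * input_hw[1] / st
      for (a in seq_len(m$na)) {
        r <- c(bwg / anch_g[a, 1], bhg / anch_g[a, 2])
        if (max(r, 1 / r) >= 4) next
        cells <- list(c(floor(bxg), floor(byg)))
        fx <- bxg %% 1; fy <- byg %% 1
        if (fx < 0.5 && bxg > 1) cells <- c(cells, list(c(floor(bxg) - 1, floor(byg))))
        if (fx >= 0.5 && bxg < gx - 1) cells <- c(cells, list(c(floor(bxg) + 1, floor(byg))))
        if (fy < 0.5 && byg > 1) cells <- c(cells, list(c(floor(bxg), floor(byg) - 1)))
        if (fy >= 0.5 && byg < gy - 1) cells <- c(cells, list(c(floor(bxg), floor(byg) + 1)))
        for (cl in cells) {
          ci <- cl[1]; cj <- cl[2]
          if (ci < 0 || cj < 0 || ci >= gx || cj >= gy) next
          rows[[length(rows) + 1L]] <-
            data.frame(bi = bi, a = a, gi = ci, gj = cj,
                       bx = bxg, by = byg, bw = bwg, bh = bhg,
                       cls = lb$class_id, ti = ti)
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  unique(do.call(rbind, rows))
}

bce_with_logits <- function(z, t) {
  # numerically stable: max(z,0) - z*t + log(1+exp(-|z|))
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# Bernoulli entropy, the soft-target BCE floor; subtracting it turns the
# objectness term into a KL divergence that vanishes on a perfect fit
# (the gradient in the logits is unchanged).
bernoulli_entropy <- function(t) {
  h <- numeric(length(t))
  i <- t > 0 & t < 1
  h[i] <- -t[i] * log(t[i]) - (1 - t[i]) * log(1 - t[i])
  h
}

#' Composite segmentation loss and head gradients for one batch
#'
#' @param m a `seg_model`.
#' @param out training-mode [seg_forward()] output.
#' @param gts list (per image) of lists of [instance_label()]s.
#' @param input_hw input (height, width) in pixels.
#' @param gains loss component gains.
#' @return list with `loss`, components, and `grads` ready for
#'   [seg_backward()].
#' @export
seg_loss <- function(m, out, gts, input_hw,
                     gains = c(box = 0.5, obj = 1.0, cls = 0.5, seg = 1.0)) {
  nb <- dim(out$p3)[4]
  npc <- 5L + m$nc + m$nm
  obj_balance <- c(4.0, 1.0, 0.4)
  raws <- list(out$p3, out$p4, out$p5)
  grads <- lapply(raws, function(r) array(0, dim = dim(r)))
  dproto <- array(0, dim = dim(out$proto))
  protod <- dim(out$proto)
  hp <- protod[2]; wp <- protod[3]
  lbox <- 0; lobj <- 0; lcls <- 0; lseg <- 0
  nbox <- 0; nseg <- 0
  for (si in 1:3) {
    raw <- raws[[si]]
    d <- dim(raw)
    tobj <- array(0, dim = c(d[2], d[3], m$na, nb))
    asg <- assign_targets(m, si, gts, input_hw)
    anch_g <- m$anchors[[si]] / m$strides[si]
    if (!is.null(asg)) for (ri in seq_len(nrow(asg))) {
      t <- asg[ri, ]
      off <- (t$a - 1L) * npc
      iy <- t$gj + 1L; ix <- t$gi + 1L
      txy <- raw[off + 1:2, iy, ix, t$bi]
      twh <- raw[off + 3:4, iy, ix, t$bi]
      sxy <- sigmoid(txy); swh <- sigmoid(twh)
      px <- 2 * sxy[1] - 0.5 + t$gi
      py <- 2 * sxy[2] - 0.5 + t$gj
      pw <- (2 * swh[1])^2 * anch_g[t$a, 1]
      ph <- (2 * swh[2])^2 * anch_g[t$a, 2]
      bg <- box_iou_grad(c(px, py, pw, ph), c(t$bx, t$by, t$bw, t$bh))
      lbox <- lbox + bg$loss
      nbox <- nbox + 1
      dbox <- bg$grad_loss
      dtx <- dbox[1] * 2 * sxy[1] * (1 - sxy[1])
      dty <- dbox[2] * 2 * sxy[2] * (1 - sxy[2])
      dtw <- dbox[3] * 8 * swh[1]^2 * (1 - swh[1]) * anch_g[t$a, 1]
      dth <- dbox[4] * 8 * swh[2]^2 * (1 - swh[2]) * anch_g[t$a, 2]
      grads[[si]][off + 1:2, iy, ix, t$bi] <-
        grads[[si]][off + 1:2, iy, ix, t$bi] + c(dtx, dty)
      grads[[si]][off + 3:4, iy, ix, t$bi] <-
        grads[[si]][off + 3:4, iy, ix, t$bi] + c(dtw, dth)
      # IoU-valued objectness target (detached from the box gradient), so
      # the confidence head learns to rank by localization quality
      tobj[iy, ix, t$a, t$bi] <- max(tobj[iy, ix, t$a, t$bi],
                                     max(bg$iou, 0.05))
      # class BCE on the nc class logits
      tclsv <- raw[off + 5L + seq_len(m$nc), iy, ix, t$bi]
      tgt <- as.numeric(seq_len(m$nc) == t$cls + 1L)
      lcls <- lcls + sum(bce_with_logits(tclsv, tgt))
      grads[[si]][off + 5L + seq_len(m$nc), iy, ix, t$bi] <-
        grads[[si]][off + 5L + seq_len(m$nc), iy, ix, t$bi] +
        (sigmoid(tclsv) - tgt)
      # mask loss: proto-combined logits, cropped to the gt box
      lb <- gts[[t$bi]][[t$ti]]
      gm <- downsample_mask(lb$mask, hp, wp)
      x1 <- max(1L, floor((lb$bbox[1] - lb$bbox[3] / 2) * wp) + 1L)
      x2 <- min(wp, ceiling((lb$bbox[1] + lb$bbox[3] / 2) * wp))
      y1 <- max(1L, floor((lb$bbox[2] - lb$bbox[4] / 2) * hp) + 1L)
      y2 <- min(hp, ceiling((lb$bbox[2] + lb$bbox[4] / 2) * hp))
      if (x2 >= x1 && y2 >= y1) {
        coef <- raw[off + 5L + m$nc + seq_len(m$nm), iy, ix, t$bi]
        pm <- matrix(out$proto[, , , t$bi], nrow = m$nm)
        logit <- matrix(as.numeric(coef %*% pm), hp, wp)
        narea <- (y2 - y1 + 1) * (x2 - x1 + 1)
        sub <- logit[y1:y2, x1:x2]
        gsub <- gm[y1:y2, x1:x2]
        lseg <- lseg + sum(bce_with_logits(sub, gsub)) / narea
        nseg <- nseg + 1
        dlog <- matrix(0, hp, wp)
        dlog[y1:y2, x1:x2] <- (sigmoid(sub) - gsub) / narea
        dcoef <- as.numeric(pm %*% as.numeric(dlog))
        grads[[si]][off + 5L + m$nc + seq_len(m$nm), iy, ix, t$bi] <-
          grads[[si]][off + 5L + m$nc + seq_len(m$nm), iy, ix, t$bi] + dcoef
        dproto[, , , t$bi] <- dproto[, , , t$bi] +
          array(outer(coef, as.numeric(dlog)), dim = c(m$nm, hp, wp))
      }
    }
    # objectness over every cell/anchor; the positive population is also
    # averaged on its own so a handful of object cells is not drowned by the
    # background mean (the two normalizations coincide up to a constant at
    # full batch scale)
    ncell <- prod(dim(tobj))
    npos <- max(sum(tobj > 0), 1)
    for (a in seq_len(m$na)) {
      off <- (a - 1L) * npc
      z <- raw[off + 5L, , , , drop = FALSE]
      tv <- tobj[, , a, , drop = FALSE]
      zt <- array(z, dim = dim(z)[2:4])
      tvv <- array(tv, dim = dim(z)[2:4])
      posw <- 1 / ncell + (tvv > 0) / npos
      lobj <- lobj + obj_balance[si] *
        sum((bce_with_logits(zt, tvv) - bernoulli_entropy(tvv)) * posw)
      gobj <- gains["obj"] * obj_balance[si] * (sigmoid(zt) - tvv) * posw
      grads[[si]][off + 5L, , , ] <- grads[[si]][off + 5L, , , ] +
        as.numeric(gobj)
    }
  }
  nbox <- max(nbox, 1); nseg <- max(nseg, 1)
  # scale the accumulated per-assignment gradients by gains / counts
  for (si in 1:3) {
    d <- dim(raws[[si]])
    for (a in seq_len(m$na)) {
      off <- (a - 1L) * npc
      grads[[si]][off + 1:4, , , ] <-
        grads[[si]][off + 1:4, , , ] * gains["box"] / nbox
      grads[[si]][off + 5L + seq_len(m$nc), , , ] <-
        grads[[si]][off + 5L + seq_len(m$nc), , , ] * gains["cls"] / nbox
      grads[[si]][off + 5L + m$nc + seq_len(m$nm), , , ] <-
        grads[[si]][off + 5L + m$nc + seq_len(m$nm), , , ] * gains["seg"] / nseg
    }
  }
  loss <- gains["box"] * lbox / nbox + gains["obj"] * lobj +
    gains["cls"] * lcls / nbox + gains["seg"] * lseg / nseg
  list(loss = as.numeric(loss),
       box = lbox / nbox, obj = lobj, cls = lcls / nbox, seg = lseg / nseg,
       grads = list(p3 = grads[[1]], p4 = grads[[2]], p5 = grads[[3]],
                    proto = gains["seg"] * dproto / nseg))
}

downsample_mask <- function(mask, hp, wp) {
  h <- nrow(mask); w <- ncol(mask)
  ys <- pmin(h, pmax(1, round((seq_len(hp) - 0.5) * h / hp + 0.5)))
  xs <- pmin(w, pmax(1, round((seq_len(wp) - 0.5) * w / wp + 0.5)))
  (mask[ys, xs, drop = FALSE]) * 1
}

#' Refresh batch-norm running statistics with frozen weights
#'
#' One pass over the given inputs in training mode (no gradient step), with
#' the momentum replaced by cumulative averaging, leaves every running
#' mean/variance equal to the statistics of this population under the
#' current weights ("precise BN"). [train()] calls this before each
#' evaluation probe and before returning, so inference-mode normalization
#' reflects the final weights rather than an exponential tail of the
#' training trajectory.
#'
#' @param m a `seg_model`.
#' @param xs list of preprocessed inputs (feature maps `(3, h, w, 1)`).
#' @param batch_size images per recalibration forward pass.
#' @return the model, invisibly.
#' @export
recalibrate_bn <- function(m, xs, batch_size = length(xs)) {
  bns <- Filter(function(l) inherits(l, "batchnorm2d"), nn_leaves(m))
  if (length(bns) == 0 || length(xs) == 0) return(invisible(m))
  sav <- vapply(bns, function(b) b$momentum, numeric(1))
  i <- 0L
  for (bs in split(seq_along(xs), ceiling(seq_along(xs) / batch_size))) {
    i <- i + 1L
    for (b in bns) b$momentum <- 1 / i
    d1 <- dim(unclass(xs[[bs[1]]]))
    xb <- array(0, dim = c(d1[1:3], length(bs)))
    for (j in seq_along(bs)) xb[, , , j] <- unclass(xs[[bs[j]]])
    invisible(seg_forward(m, as_fm(xb), train = TRUE))
  }
  for (k in seq_along(bns)) bns[[k]]$momentum <- sav[k]
  invisible(m)
}

#' Train a segmentation model on an in-memory dataset
#'
#' Images are letterboxed to the model input size once; SGD with momentum
#' runs `cfg$epochs` passes with a short linear warmup. The checkpoint with
#' the best training-set mAP@50 (evaluated every `eval_every` epochs) is
#' returned together with the final state and the loss log. A NaN loss
#' aborts with a diagnostic naming the offending batch.
#'
#' @param m a `seg_model`.
#' @param dataset list with `images` (matrices, 0-255) and `labels`.
#' @param cfg a [train_config()].
#' @param eval_every epochs between mAP probes (0 = never).
#' @param verbose print per-epoch loss.
#' @return a checkpoint list: `state`, `best_state`, `log`, `cfg`.
#' @export
train <- function(m, dataset, cfg = train_config(), eval_every = 0L,
                  verbose = FALSE) {
  n <- length(dataset$images)
  if (n == 0) stop("train: dataset is empty")
  size <- m$cfg$input_size[1]
  prep <- lapply(seq_len(n), function(i)
    preprocess(dataset$images[[i]], size, dataset$labels[[i]]))
  xs <- lapply(prep, `[[`, "x")
  lbs <- lapply(prep, `[[`, "labels")
  params <- nn_params(m)
  set.seed(cfg$seed)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    map50 = numeric(0))
  best <- list(map = -1, state = NULL)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      step <- step + 1L
      # short linear warmup, then linear decay to 0.1 * lr0
      decay <- 1 - 0.9 * (ep - 1) / max(cfg$epochs - 1, 1)
      lr <- cfg$lr0 * min(1, 0.1 + 0.9 * step / 20) * decay
      xb <- array(0, dim = c(3, size, size, length(bs)))
      for (i in seq_along(bs)) xb[, , , i] <- xs[[bs[i]]]
      out <- seg_forward(m, as_fm(xb), train = TRUE)
      ls <- seg_loss(m, out, lbs[bs], c(size, size))
      if (!is.finite(ls$loss))
        stop("train: non-finite loss at epoch ", ep, ", batch of images ",
             paste(bs, collapse = ","))
      seg_backward(m, ls$grads)
      sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + ls$loss; nb <- nb + 1
    }
    map50 <- NA_real_
    if (eval_every > 0 && (ep %% eval_every == 0 || ep == cfg$epochs)) {
      recalibrate_bn(m, xs)
      er <- evaluate(m, dataset, thresholds = 0.5)[[1]]
      map50 <- er$map50
      if (!is.na(map50) && map50 > best$map)
        best <- list(map = map50, state = get_weights(m))
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb,
                                 map50 = map50))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  mAP50 %s\n", ep, ep_loss / nb,
                  ifelse(is.na(map50), "-", sprintf("%.3f", map50))))
  }
  recalibrate_bn(m, xs)
  list(state = get_weights(m), best_state = best$state, log = log,
       cfg = cfg, model_cfg = m$cfg)
}

#' Evaluate a model on a dataset at one or more matching thresholds
#'
#' @param m a `seg_model`.
#' @param dataset list with `images` and `labels`.
#' @param thresholds matching IoU thresholds (one [eval_report()] each).
#' @param conf_thr,nms_iou inference settings.
#' @param iou_type `"mask"` or `"box"` matching.
#' @return named list of `eval_report`s.
#' @export
evaluate <- function(m, dataset, thresholds = c(0.6, 0.7, 0.8, 0.9),
                     conf_thr = 0.001, nms_iou = 0.45, iou_type = "mask") {
  size <- m$cfg$input_size[1]
  n <- length(dataset$images)
  preds <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    pp <- preprocess(dataset$images[[i]], size, dataset$labels[[i]])
    preds[[i]] <- forward_predict(m, unclass(pp$x), conf_thr, nms_iou)[[1]]
    gts[[i]] <- lapply(pp$labels, function(lb) {
      lb$mask <- rasterize_polygon(lb$polygon, size, size)
      lb
    })
  }
  out <- lapply(thresholds, function(th)
    eval_report(preds, gts, matching_iou = th, iou_type = iou_type,
                num_classes = m$nc))
  names(out) <- sprintf("iou_%.2f", thresholds)
  out
}

#' Per-image timing breakdown: preprocess / inference / NMS
#'
#' @param m a `seg_model`.
#' @param images list of raw image matrices.
#' @param n_warmup leading iterations excluded from the means.
#' @return a `timing_report` with per-image millisecond means.
#' @export
timing_breakdown <- function(m, images, n_warmup = 1L) {
  stopifnot(n_warmup >= 1)
  size <- m$cfg$input_size[1]
  tp <- ti <- tn <- numeric(0)
  runs <- c(rep(TRUE, n_warmup), rep(FALSE, length(images)))
  imgs <- c(images[seq_len(min(n_warmup, length(images)))], images)
  for (i in seq_along(imgs)) {
    t0 <- Sys.time()
    pp <- preprocess(imgs[[i]], size)
    t1 <- Sys.time()
    out <- seg_forward(m, pp$x, train = FALSE)
    t2 <- Sys.time()
    invisible(decode_and_nms(m, out, size))
    t3 <- Sys.time()
    if (i > n_warmup) {
      tp <- c(tp, as.numeric(t1 - t0, units = "secs") * 1000)
      ti <- c(ti, as.numeric(t2 - t1, units = "secs") * 1000)
      tn <- c(tn, as.numeric(t3 - t2, units = "secs") * 1000)
    }
  }
  structure(list(preprocess_ms = mean(tp), inference_ms = mean(ti),
                 nms_ms = mean(tn)), class = "timing_report")
}

decode_and_nms <- function(m, out, size, conf_thr = 0.25, nms_iou = 0.45) {
  cand <- rbind(decode_scale(m, out$p3, 1L, 1L),
                decode_scale(m, out$p4, 2L, 1L),
                decode_scale(m, out$p5, 3L, 1L))
  cand <- cand[cand$conf > conf_thr, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  boxes <- cbind(cand$px - cand$pw / 2, cand$py - cand$ph / 2,
                 cand$px + cand$pw / 2, cand$py + cand$ph / 2)
  keep <- integer(0)
  for (cl in unique(cand$class_id)) {
    sel <- which(cand$class_id == cl)
    keep <- c(keep, sel[nms_greedy(boxes[sel, , drop = FALSE],
                                   cand$conf[sel], nms_iou)])
  }
  cand[keep, , drop = FALSE]
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("%-18s %-18s %-10s\n", "Pre-process (ms)", "Inference (ms)",
              "NMS (ms)"))
  cat(sprintf("%-18.2f %-18.2f %-10.2f\n", x$preprocess_ms, x$inference_ms,
              x$nms_ms))
  invisible(x)
}
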