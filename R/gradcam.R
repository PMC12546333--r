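# Grad-CAM over the backbone-tail module output: channel weights are the
# spatially pooled gradients of a target class-confidence logit, the heatmap
# is the rectified weighted channel sum, upsampled to image size and min-max
# normalized.

#' Grad-CAM heatmap for one image
#'
#' The target score is the class-confidence logit of the strongest
#' prediction of `target_class` (falling back to the strongest cell overall
#' when nothing clears the confidence threshold).
#'
#' @param m a `seg_model`.
#' @param image raw image matrix (0-255) or a preprocessed `(3,H,W,1)` array.
#' @param target_class class id (0-based); default: the best prediction's.
#' @param conf_thr candidate threshold used to pick the target prediction.
#' @param .score_grad gradient injected at the target logit (the heatmap is
#'   invariant to this positive scale; exposed for exactly that check).
#' @return a `heatmap` list: `values` (H x W, in \[0, 1\]), `layer_name`,
#'   `target`.
#' @export
gradcam <- function(m, image, target_class = NULL, conf_thr = 0.001,
                    .score_grad = 1) {
  size <- m$cfg$input_size[1]
  x <- if (length(dim(image)) == 4L) image else preprocess(image, size)$x
  out <- seg_forward(m, as_fm(x), train = TRUE)
  cand <- rbind(decode_scale(m, out$p3, 1L, 1L),
                decode_scale(m, out$p4, 2L, 1L),
                decode_scale(m, out$p5, 3L, 1L))
  if (!is.null(target_class)) {
    sel <- cand[cand$class_id == target_class & cand$conf > conf_thr, ,
                drop = FALSE]
    if (nrow(sel) == 0) sel <- cand[cand$class_id == target_class, ,
                                    drop = FALSE]
  } else sel <- cand
  best <- sel[which.max(sel$conf), ]
  npc <- 5L + m$nc + m$nm
  grads <- list(p3 = array(0, dim = dim(out$p3)),
                p4 = array(0, dim = dim(out$p4)),
                p5 = array(0, dim = dim(out$p5)),
                proto = array(0, dim = dim(out$proto)))
  gy <- dim(out[[c("p3", "p4", "p5")[best$scale]]])[2]
  iy <- (best$cell - 1L) %% gy + 1L
  ix <- (best$cell - 1L) %/% gy + 1L
  ch <- (best$anchor - 1L) * npc + 5L + best$class_id + 1L
  grads[[best$scale]][ch, iy, ix, 1L] <- .score_grad
  zero_grads(m)
  seg_backward(m, grads)
  g <- m$grad_tail_out          # (C, h, w, 1)
  a <- out$tail_out
  d <- dim(g)
  alpha <- rowMeans(matrix(g, nrow = d[1]))
  cam <- matrix(as.numeric(alpha %*% matrix(a, nrow = d[1])), d[2], d[3])
  cam <- pmax(cam, 0)
  zero_grads(m)
  up <- t(as.matrix(EBImage::resize(EBImage::Image(t(cam)), w = size,
                                    h = size)))
  rng <- range(up)
  if (rng[2] > rng[1]) up <- (up - rng[1]) / (rng[2] - rng[1])
  else {
    warning("gradcam: zero gradient everywhere; returning an empty heatmap")
    up <- matrix(0, size, size)
  }
  structure(list(values = up, layer_name = "tail",
                 target = list(class_id = best$class_id,
                               conf = best$conf)),
            class = "heatmap")
}

#' Alpha-blend a colormapped heatmap onto a grayscale image
#'
#' @param image matrix (0-255) sized like the heatmap.
#' @param heatmap a [gradcam()] result or matrix in \[0, 1\].
#' @param alpha blend weight in \[0, 1\] (0 = image only, 1 = heatmap only).
#' @param path optional PNG output path.
#' @return the blended H x W x 3 array (0-255), invisibly when written.
#' @export
overlay <- function(image, heatmap, alpha = 0.5, path = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  if (!identical(dim(image), dim(hv)))
    stop("overlay: image and heatmap shapes differ")
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cm <- ramp(as.numeric(hv))            # n x 3, 0-255
  out <- array(0, dim = c(nrow(image), ncol(image), 3L))
  for (ci in 1:3)
    out[, , ci] <- (1 - alpha) * image + alpha * matrix(cm[, ci], nrow(image))
  out <- pmin(pmax(out, 0), 255)
  if (!is.null(path)) {
    png::writePNG(out / 255, path)
    return(invisible(out))
  }
  out
}

#' Fraction of heatmap mass inside a mask, per unit area
#'
#' Density ratio used to quantify lesion focus: mean heatmap value inside
#' the mask divided by the mean outside.
#'
#' @param heatmap a [gradcam()] result or matrix.
#' @param mask logical matrix of the same shape.
#' @return density ratio (> 1 means the heatmap concentrates on the mask).
#' @export
heatmap_focus_ratio <- function(heatmap, mask) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  stopifnot(identical(dim(hv), dim(mask)))
  inside <- mean(hv[mask])
  outside <- mean(hv[!mask])
  if (outside == 0) return(Inf)
  inside / outside
}
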