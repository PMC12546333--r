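# Evaluation metrics for detection / instance segmentation: greedy one-to-one
# IoU matching within class, precision, recall, average precision as the area
# under the monotone precision envelope, and mAP@50.

#' Instance ground-truth label
#'
#' @param class_id integer class (0-based, YOLO convention).
#' @param polygon matrix (n x 2) of normalized (x, y) vertices, n >= 3.
#' @param mask optional logical raster; rasterized from the polygon when
#'   omitted (`mask_size` pixels square).
#' @param mask_size raster size used when `mask` is missing.
#' @return an `instance_label` with fields class_id, polygon, bbox
#'   (cx, cy, w, h normalized) and mask.
#' @export
instance_label <- function(class_id, polygon, mask = NULL, mask_size = 160L) {
  stopifnot(nrow(polygon) >= 3L)
  if (any(polygon < -1e-9) || any(polygon > 1 + 1e-9))
    stop("instance_label: polygon must be normalized to [0,1]")
  xs <- range(polygon[, 1]); ys <- range(polygon[, 2])
  bbox <- c(cx = mean(xs), cy = mean(ys), w = diff(xs), h = diff(ys))
  if (is.null(mask)) mask <- rasterize_polygon(polygon, mask_size, mask_size)
  if (!any(mask)) stop("instance_label: mask is empty")
  structure(list(class_id = as.integer(class_id), polygon = polygon,
                 bbox = bbox, mask = mask),
            class = "instance_label")
}

#' Rasterize a normalized polygon to a logical mask (even-odd rule)
#'
#' Pixel centers are tested against the polygon with the even-odd crossing
#' rule; the raster uses matrix convention (rows = y).
#'
#' @param polygon matrix (n x 2), normalized (x, y).
#' @param h,w raster size in pixels.
#' @return logical h x w matrix.
#' @export
rasterize_polygon <- function(polygon, h, w) {
  px <- polygon[, 1] * w
  py <- polygon[, 2] * h
  n <- length(px)
  xs <- rep((seq_len(w) - 0.5), each = h)
  ys <- rep((seq_len(h) - 0.5), w)
  inside <- logical(h * w)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys))
    if (any(crosses)) {
      xint <- (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i]
      inside <- xor(inside, crosses & (xs < xint))
    }
    j <- i
  }
  matrix(inside, h, w)
}

#' IoU of two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return intersection / union. Both masks empty is an error (undefined
#'   IoU), not 0.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) stop("mask_iou: both masks empty; IoU undefined")
  sum(a & b) / u
}

#' Greedy one-to-one matching of predictions to ground truths
#'
#' Predictions are processed in decreasing confidence; each one matches the
#' highest-IoU not-yet-matched ground truth of the same class with
#' IoU >= `iou_thr` (true positive), otherwise it is a false positive.
#' Unmatched ground truths are false negatives.
#'
#' @param pred_classes,pred_conf per-prediction class and confidence.
#' @param iou_matrix npred x ngt IoU matrix (any IoU flavor: box or mask).
#' @param gt_classes per-ground-truth class.
#' @param iou_thr matching threshold in (0, 1].
#' @return a `match_counts` list: tp, fp, fn and the per-confidence ranked
#'   flags (data.frame conf, tp).
#' @export
match_instances <- function(pred_classes, pred_conf, iou_matrix, gt_classes,
                            iou_thr = 0.5) {
  if (iou_thr <= 0 || iou_thr > 1) stop("match_instances: iou_thr must be in (0,1]")
  np <- length(pred_classes); ng <- length(gt_classes)
  ord <- order(pred_conf, decreasing = TRUE)
  gt_used <- rep(FALSE, ng)
  flags <- logical(np)
  for (oi in seq_along(ord)) {
    i <- ord[oi]
    best_j <- 0L; best_iou <- -1
    for (j in seq_len(ng)) {
      if (gt_used[j] || gt_classes[j] != pred_classes[i]) next
      v <- iou_matrix[i, j]
      if (v >= iou_thr && v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0L) { gt_used[best_j] <- TRUE; flags[i] <- TRUE }
  }
  tp <- sum(flags)
  structure(list(tp = tp, fp = np - tp, fn = ng - tp,
                 ranked = data.frame(conf = pred_conf[ord],
                                     tp = flags[ord])),
            class = "match_counts")
}

#' Precision TP / (TP + FP)
#' @param c a `match_counts`.
#' @return precision, or `NA` when no predictions exist (undefined).
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) return(NA_real_)
  c$tp / (c$tp + c$fp)
}

#' Recall TP / (TP + FN)
#' @param c a `match_counts`.
#' @return recall, or `NA` when no ground truths exist (undefined).
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) return(NA_real_)
  c$tp / (c$tp + c$fn)
}

#' Average precision: area under the precision-recall envelope
#'
#' All-point interpolation: the precision curve is made monotonically
#' non-increasing from the right, then integrated over recall.
#'
#' @param ranked_flags logical TP flags ordered by decreasing confidence.
#' @param n_gt number of ground-truth instances.
#' @return AP in \[0, 1\], or `NA` when `n_gt` is 0 (undefined).
#' @export
average_precision <- function(ranked_flags, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(ranked_flags) == 0) return(0)
  tp_cum <- cumsum(ranked_flags)
  fp_cum <- cumsum(!ranked_flags)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  # monotone envelope from the right
  env <- rev(cummax(rev(prec)))
  r_prev <- 0
  ap <- 0
  for (i in seq_along(rec)) {
    ap <- ap + (rec[i] - r_prev) * env[i]
    r_prev <- rec[i]
  }
  ap
}

#' Mean average precision over classes (matching IoU 0.5)
#'
#' @param ap_per_class numeric vector of per-class APs (NA = undefined).
#' @return unweighted mean of the defined APs; error if all are undefined.
#' @export
map_at_50 <- function(ap_per_class) {
  ok <- !is.na(ap_per_class)
  if (!any(ok)) stop("map_at_50: AP undefined for every class")
  mean(ap_per_class[ok])
}

#' Full evaluation report for a set of images
#'
#' Greedy matching at `matching_iou` yields the TP/FP/FN counts behind
#' precision and recall; AP is computed per class from confidence-ranked
#' flags. By default the AP matching threshold is pinned at 0.5 (mAP@50)
#' regardless of `matching_iou`; set `ap_at_matching_iou = TRUE` to let it
#' follow `matching_iou`.
#'
#' @param preds list of `prediction_set`s (one per image).
#' @param gts list of lists of `instance_label`s (one list per image).
#' @param matching_iou IoU threshold for the TP/FP/FN counts.
#' @param iou_type `"mask"` (default) or `"box"`.
#' @param num_classes number of classes.
#' @param ap_at_matching_iou see above.
#' @return an `eval_report`: precision, recall, ap_per_class, map50,
#'   matching_iou.
#' @export
eval_report <- function(preds, gts, matching_iou = 0.5, iou_type = "mask",
                        num_classes = 2L, ap_at_matching_iou = FALSE) {
  iou_type <- match.arg(iou_type, c("mask", "box"))
  per_image <- lapply(seq_along(preds), function(i)
    image_iou_matrix(preds[[i]], gts[[i]], iou_type))
  agg <- function(thr) {
    tp <- 0L; fp <- 0L; fn <- 0L
    flags_by_class <- lapply(seq_len(num_classes), function(k)
      data.frame(conf = numeric(0), tp = logical(0)))
    ngt_by_class <- integer(num_classes)
    for (i in seq_along(preds)) {
      pim <- per_image[[i]]
      mc <- match_instances(pim$pred_classes, pim$pred_conf, pim$iou,
                            pim$gt_classes, thr)
      tp <- tp + mc$tp; fp <- fp + mc$fp; fn <- fn + mc$fn
      for (k in seq_len(num_classes)) {
        cl <- k - 1L
        sel <- pim$pred_classes[order(pim$pred_conf,
                                      decreasing = TRUE)] == cl
        flags_by_class[[k]] <- rbind(flags_by_class[[k]],
                                     mc$ranked[sel, , drop = FALSE])
        ngt_by_class[k] <- ngt_by_class[k] + sum(pim$gt_classes == cl)
      }
    }
    list(tp = tp, fp = fp, fn = fn, flags = flags_by_class,
         ngt = ngt_by_class)
  }
  a <- agg(matching_iou)
  ap_src <- if (ap_at_matching_iou || matching_iou == 0.5) a else agg(0.5)
  ap <- vapply(seq_len(num_classes), function(k) {
    if (ap_src$ngt[k] == 0) return(NA_real_)
    fl <- ap_src$flags[[k]]
    fl <- fl[order(fl$conf, decreasing = TRUE), , drop = FALSE]
    average_precision(fl$tp, ap_src$ngt[k])
  }, numeric(1))
  counts <- structure(list(tp = a$tp, fp = a$fp, fn = a$fn),
                      class = "match_counts")
  structure(list(precision = precision(counts), recall = recall(counts),
                 ap_per_class = ap, map50 = map_at_50(ap),
                 matching_iou = matching_iou,
                 tp = a$tp, fp = a$fp, fn = a$fn),
            class = "eval_report")
}

image_iou_matrix <- function(pred, gt_list, iou_type) {
  np <- nrow(pred$boxes); ng <- length(gt_list)
  iou <- matrix(0, np, ng)
  if (np > 0 && ng > 0) {
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      if (iou_type == "box") {
        pb <- as.numeric(pred$boxes[i, c("cx", "cy", "w", "h")])
        gb <- gt_list[[j]]$bbox
        a <- matrix(c(pb[1] - pb[3] / 2, pb[2] - pb[4] / 2,
                      pb[1] + pb[3] / 2, pb[2] + pb[4] / 2), 1)
        b <- matrix(c(gb[1] - gb[3] / 2, gb[2] - gb[4] / 2,
                      gb[1] + gb[3] / 2, gb[2] + gb[4] / 2), 1)
        iou[i, j] <- box_iou_xyxy(a, b)[1, 1]
      } else {
        pm <- pred$masks[[i]]
        gm <- gt_list[[j]]$mask
        if (!identical(dim(pm), dim(gm)))
          gm <- rasterize_polygon(gt_list[[j]]$polygon, nrow(pm), ncol(pm))
        iou[i, j] <- if (!any(pm) && !any(gm)) 0 else
          sum(pm & gm) / sum(pm | gm)
      }
    }
  }
  list(iou = iou, pred_classes = pred$boxes$class_id,
       pred_conf = pred$boxes$conf,
       gt_classes = vapply(gt_list, function(g) g$class_id, integer(1)))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval report (matching IoU %.2f)\n", x$matching_iou))
  cat(sprintf("  precision %.3f  recall %.3f  mAP@50 %.3f\n",
              x$precision, x$recall, x$map50))
  invisible(x)
}
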