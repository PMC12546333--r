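# Metrics: IoU primitives, greedy matching against an exhaustive oracle,
# precision/recall/AP closed forms, threshold monotonicity.

test_that("mask IoU: identity, disjoint, hand-counted overlap, empty error", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  cc <- matrix(FALSE, 4, 4); cc[2:3, 1:2] <- TRUE   # overlaps a on 2 cells
  expect_equal(mask_iou(a, cc), 2 / 6, tolerance = 1e-12)
  e <- matrix(FALSE, 4, 4)
  expect_error(mask_iou(e, e), "undefined")
})

test_that("greedy matching handles the printed counting cases", {
  # exact self-match
  m <- match_instances(0L, 0.9, matrix(1, 1, 1), 0L, 0.6)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  # two identical predictions on one gt: one-to-one guard
  m2 <- match_instances(c(0L, 0L), c(0.9, 0.8), matrix(1, 2, 1), 0L, 0.6)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  # pairwise IoUs {0.95, 0.65, 0.55}: the 0.55 pair fails the 0.6 threshold
  iou <- diag(c(0.95, 0.65, 0.55))
  m3 <- match_instances(rep(0L, 3), c(0.9, 0.8, 0.7), iou, rep(0L, 3), 0.6)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2L, 1L, 1L))
  expect_equal(m3$tp, brute_force_tp(rep(0L, 3), iou, rep(0L, 3), 0.6))
  expect_error(match_instances(0L, 0.9, matrix(1, 1, 1), 0L, 1.5), "iou_thr")
})

test_that("greedy matching is bounded by and usually equals the optimum", {
  # Greedy-by-confidence (the standard evaluator rule) can be strictly below
  # the optimal assignment when two predictions compete for the same ground
  # truth, so the exact oracle properties are: never above the optimum, and
  # equal whenever no competition is possible (single prediction or single
  # ground truth per class).
  set.seed(40)
  for (trial in 1:40) {
    np <- sample(1:4, 1); ng <- sample(1:4, 1)
    # distinct IoUs on a 0.06-step grid => pairwise gaps exceed 0.05
    iou <- matrix(sample(seq(0.02, 0.98, by = 0.06), np * ng), np, ng)
    pc <- sample(0:1, np, replace = TRUE)
    gc <- sample(0:1, ng, replace = TRUE)
    thr <- sample(c(0.45, 0.65), 1)
    m <- match_instances(pc, runif(np), iou, gc, thr)
    opt <- brute_force_tp(pc, iou, gc, thr)
    expect_lte(m$tp, opt)
    if (np == 1 || ng == 1)
      expect_equal(m$tp, opt, label = paste("trial", trial))
  }

  # the canonical counterexample: the confident prediction grabs the ground
  # truth its rival needed, so greedy finds 1 TP where the optimum finds 2
  iou <- matrix(c(0.8, 0.0, 0.9, 0.7), 2, 2)
  expect_equal(brute_force_tp(c(0L, 0L), iou, c(0L, 0L), 0.65), 2L)
  m <- match_instances(c(0L, 0L), c(0.9, 0.1), iou, c(0L, 0L), 0.65)
  expect_equal(m$tp, 1L)
})

test_that("precision and recall closed forms and undefined cases", {
  mk <- function(tp, fp, fn) structure(list(tp = tp, fp = fp, fn = fn),
                                       class = "match_counts")
  expect_equal(precision(mk(9, 1, 0)), 0.9)
  expect_equal(precision(mk(5, 0, 2)), 1.0)
  expect_equal(precision(mk(3, 1, 0)), 0.75)
  expect_true(is.na(precision(mk(0, 0, 3))))
  expect_equal(recall(mk(9, 0, 1)), 0.9)
  expect_equal(recall(mk(4, 2, 0)), 1.0)
  expect_equal(recall(mk(1, 0, 3)), 0.25)
  expect_true(is.na(recall(mk(0, 2, 0))))
})

test_that("average precision reproduces the envelope integral", {
  expect_equal(average_precision(TRUE, 1), 1.0)
  # ranked [TP, FP, TP] with 2 gts: AP = 1 * 0.5 + (2/3) * 0.5
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               1 * 0.5 + (2 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(average_precision(c(FALSE, FALSE), 3), 0)
  expect_true(is.na(average_precision(logical(0), 0)))
  # AP = 1 iff every gt is matched before any false positive
  expect_equal(average_precision(c(TRUE, TRUE, FALSE), 2), 1)
  expect_lt(average_precision(c(FALSE, TRUE, TRUE), 2), 1)
})

test_that("mAP@50 is the unweighted class mean; single class passes through", {
  expect_equal(map_at_50(c(0.8, 0.6)), 0.7)
  expect_equal(map_at_50(c(0.42, NA)), 0.42)
  expect_error(map_at_50(c(NA_real_, NA_real_)), "undefined")
})

test_that("tp never rises and fn never falls as the threshold climbs", {
  set.seed(41)
  for (trial in 1:10) {
    np <- sample(2:6, 1); ng <- sample(2:6, 1)
    iou <- matrix(runif(np * ng), np, ng)
    pc <- sample(0:1, np, replace = TRUE)
    gc <- sample(0:1, ng, replace = TRUE)
    conf <- runif(np)
    prev_tp <- Inf; prev_fn <- -Inf
    for (thr in c(0.6, 0.7, 0.8, 0.9)) {
      m <- match_instances(pc, conf, iou, gc, thr)
      expect_lte(m$tp, prev_tp)
      expect_gte(m$fn, prev_fn)
      prev_tp <- m$tp; prev_fn <- m$fn
    }
  }
})

test_that("polygon rasterization matches an analytic rectangle", {
  poly <- cbind(c(0.25, 0.75, 0.75, 0.25), c(0.25, 0.25, 0.75, 0.75))
  m <- rasterize_polygon(poly, 40, 40)
  expect_equal(sum(m), 20 * 20)
  expect_true(m[20, 20] && !m[5, 5])
})

test_that("instance labels derive bbox from the polygon and demand 3 vertices", {
  poly <- cbind(c(0.2, 0.6, 0.4), c(0.3, 0.3, 0.7))
  lb <- instance_label(1L, poly)
  expect_equal(as.numeric(lb$bbox), c(0.4, 0.5, 0.4, 0.4))
  expect_error(instance_label(0L, poly[1:2, ]))
  expect_error(instance_label(0L, poly * 3), "normalized")
})

test_that("an eval report over a perfect predictor scores 1 everywhere", {
  set.seed(42)
  gts <- lapply(1:3, function(i) {
    poly <- cbind(c(0.3, 0.7, 0.7, 0.3), c(0.3, 0.3, 0.7, 0.7)) +
      (i - 2) * 0.05
    list(instance_label(i %% 2, poly, mask_size = 64))
  })
  preds <- lapply(gts, function(g) {
    lb <- g[[1]]
    structure(list(
      boxes = data.frame(class_id = lb$class_id, conf = 0.9,
                         cx = lb$bbox[1], cy = lb$bbox[2],
                         w = lb$bbox[3], h = lb$bbox[4]),
      masks = list(lb$mask)), class = "prediction_set")
  })
  for (thr in c(0.6, 0.9)) {
    r <- eval_report(preds, gts, matching_iou = thr)
    expect_equal(r$precision, 1)
    expect_equal(r$recall, 1)
    expect_equal(r$map50, 1)
  }
  rb <- eval_report(preds, gts, matching_iou = 0.6, iou_type = "box")
  expect_equal(rb$map50, 1)
})
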