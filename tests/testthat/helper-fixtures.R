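# Shared fixtures. The tiny-overfit checkpoint (LAAM variant, 10 phantoms,
# 120 epochs at batch 5, 96 px, quarter width) is expensive (~5 min on one
# CPU), so it is trained once per session and memoized for every test that
# needs it. Batch 5 rather than 1: with single-image batches the network
# learns to exploit per-image batch-norm statistics and inference-mode
# normalization (population statistics) no longer reproduces the fit.

.fixture_env <- new.env(parent = emptyenv())

overfit_fixture <- function() {
  if (!is.null(.fixture_env$overfit)) return(.fixture_env$overfit)
  params <- phantom_params(image_size = 96, n_images = 10, noise_sigma = 4,
                           seed = 7)
  ds <- generate_dataset(params)
  m <- build_model(model_config(input_size = 96, tail_variant = "LAAM",
                                width_multiple = 0.25, seed = 11))
  ck <- train(m, ds, train_config(batch_size = 5, lr0 = 1e-2, epochs = 120,
                                  seed = 11),
              eval_every = 30)
  .fixture_env$overfit <- list(model = m, dataset = ds, checkpoint = ck,
                               params = params)
  .fixture_env$overfit
}

# small deterministic feature map
fixture_fm <- function(c, h, w, b = 1L, seed = 1L) {
  set.seed(seed)
  feature_map(stats::rnorm(c * h * w * b), c, h, w, b)
}

# finite-difference gradient check of a layer's input gradient
fd_input_grad_ok <- function(layer, xdim, eps = 1e-5, tol = 1e-3,
                             seed = 1L) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(xdim)), dim = xdim)
  y <- nn_forward(layer, as_laam_fm(x), train = TRUE)
  dy <- array(stats::rnorm(length(y)), dim = dim(y))
  base <- sum(y * dy)
  dx <- nn_backward(layer, dy)
  idx <- sample(length(x), min(6, length(x)))
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    yp <- nn_forward(layer, as_laam_fm(xp), train = TRUE)
    nn_backward(layer, dy)
    (sum(yp * dy) - base) / eps
  }, numeric(1))
  max(abs(num - dx[idx]) / (abs(num) + 1e-3)) < tol
}

as_laam_fm <- function(x) feature_map(x)

# exhaustive optimal one-to-one assignment (oracle for greedy matching)
brute_force_tp <- function(pred_classes, iou, gt_classes, thr) {
  np <- length(pred_classes); ng <- length(gt_classes)
  best <- 0L
  assign_rec <- function(i, used, tp) {
    if (i > np) { best <<- max(best, tp); return(invisible(NULL)) }
    assign_rec(i + 1L, used, tp)                     # prediction unmatched
    for (j in seq_len(ng)) {
      if (used[j] || gt_classes[j] != pred_classes[i]) next
      if (iou[i, j] >= thr) {
        used[j] <- TRUE
        assign_rec(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1L, rep(FALSE, ng), 0L)
  best
}
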