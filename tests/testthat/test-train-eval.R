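# Training harness: loss gradients, determinism, degenerate inputs,
# evaluation self-consistency, timing report. Heavy learning checks live in
# the acceptance suite; everything here runs on 32-px models in seconds.

tiny_train_setup <- function(seed = 60) {
  params <- phantom_params(image_size = 32, n_images = 4, noise_sigma = 2,
                           seed = seed)
  ds <- generate_dataset(params)
  m <- build_model(model_config(input_size = 32, tail_variant = "LAAM",
                                width_multiple = 0.25, seed = seed))
  list(ds = ds, m = m)
}

test_that("composite loss is finite and declines over a short training run", {
  s <- tiny_train_setup()
  prep <- lapply(1:4, function(i)
    preprocess(s$ds$images[[i]], 32, s$ds$labels[[i]]))
  xb <- array(0, dim = c(3, 32, 32, 4))
  for (i in 1:4) xb[, , , i] <- prep[[i]]$x
  out <- seg_forward(s$m, feature_map(xb), train = TRUE)
  ls <- seg_loss(s$m, out, lapply(prep, `[[`, "labels"), c(32, 32))
  expect_true(is.finite(ls$loss) && ls$loss > 0)
  expect_true(all(is.finite(unlist(ls$grads))))
  # a single step is not guaranteed to lower the total: the IoU-valued
  # objectness targets move with the boxes (they are detached from the
  # gradient), so the objective is not a strict descent function. A short
  # run must decline.
  ck <- train(s$m, s$ds, train_config(batch_size = 2, lr0 = 1e-2,
                                      epochs = 10, seed = 3))
  expect_lt(ck$log$loss[10], ck$log$loss[1])
})

test_that("head-gradient direction agrees with finite differences of the loss", {
  s <- tiny_train_setup(61)
  prep <- preprocess(s$ds$images[[1]], 32, s$ds$labels[[1]])
  out <- seg_forward(s$m, prep$x, train = TRUE)
  ls <- seg_loss(s$m, out, list(prep$labels), c(32, 32))
  eps <- 1e-4
  for (nm in c("p3", "p4", "p5", "proto")) {
    g <- ls$grads[[nm]]
    idx <- order(abs(g), decreasing = TRUE)[1:3]
    for (i in idx) {
      out2 <- out
      out2[[nm]] <- out[[nm]]
      out2[[nm]][i] <- out2[[nm]][i] + eps
      ls2 <- seg_loss(s$m, out2, list(prep$labels), c(32, 32))
      expect_equal((ls2$loss - ls$loss) / eps, g[i], tolerance = 0.05,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("two runs with the same seed give identical first-epoch losses", {
  s1 <- tiny_train_setup(62)
  ck1 <- train(s1$m, s1$ds, train_config(batch_size = 2, epochs = 1,
                                         seed = 5))
  s2 <- tiny_train_setup(62)
  ck2 <- train(s2$m, s2$ds, train_config(batch_size = 2, epochs = 1,
                                         seed = 5))
  expect_identical(ck1$log$loss[1], ck2$log$loss[1])
})

test_that("empty datasets are rejected", {
  s <- tiny_train_setup(63)
  expect_error(train(s$m, list(images = list(), labels = list())), "empty")
})

test_that("evaluation of an untrained model stays well defined", {
  s <- tiny_train_setup(64)
  reps <- evaluate(s$m, s$ds, thresholds = c(0.6, 0.9), conf_thr = 0.9)
  for (r in reps) {
    expect_true(is.na(r$precision) || (r$precision >= 0 && r$precision <= 1))
    expect_equal(r$fn + r$tp, 4L)   # one gt per image
  }
})

test_that("recall is monotone non-increasing across matching thresholds", {
  fx <- overfit_fixture()
  reps <- evaluate(fx$model, fx$dataset, thresholds = c(0.6, 0.7, 0.8, 0.9))
  recalls <- vapply(reps, function(r) r$recall, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
  tps <- vapply(reps, function(r) r$tp, numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("checkpoints restore into an equivalent model", {
  fx <- overfit_fixture()
  m2 <- load_checkpoint(fx$checkpoint)
  x <- preprocess(fx$dataset$images[[1]], 96)$x
  a <- forward_predict(fx$model, unclass(x), conf_thr = 0.25)[[1]]
  b <- forward_predict(m2, unclass(x), conf_thr = 0.25)[[1]]
  expect_equal(nrow(a$boxes), nrow(b$boxes))
})

test_that("timing breakdown reports nonnegative per-phase means", {
  s <- tiny_train_setup(65)
  tr <- timing_breakdown(s$m, s$ds$images[1:2], n_warmup = 1)
  expect_true(all(c(tr$preprocess_ms, tr$inference_ms, tr$nms_ms) >= 0))
  expect_true(all(is.finite(c(tr$preprocess_ms, tr$inference_ms,
                              tr$nms_ms))))
  txt <- capture.output(print(tr))
  expect_match(txt[1], "Pre-process")
  expect_match(txt[1], "NMS")
})
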