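# Model assembly: slot isolation, end-to-end differentiability, NMS
# behaviour, input validation. All forwards run at 32-64 px with quarter
# width; the architecture is identical at any size divisible by 32.

tiny_cfg <- function(variant, size = 64, seed = 1)
  model_config(input_size = size, tail_variant = variant,
               width_multiple = 0.25, seed = seed)

test_that("input size must be divisible by the deepest stride", {
  expect_error(model_config(input_size = 100), "divisible by 32")
  expect_silent(model_config(input_size = 64))
})

test_that("swapping the tail never touches non-tail parameter shapes", {
  set.seed(50)
  shapes <- lapply(c("SPP", "ASPP", "LAAM", "LASPP"), function(v) {
    m <- build_model(tiny_cfg(v))
    param_shapes(m)
  })
  ref <- shapes[[1]]
  for (s in shapes[-1]) {
    a <- ref[ref$layer != "tail", ]
    b <- s[s$layer != "tail", ]
    expect_identical(a$shape, b$shape)
    expect_identical(a$layer, b$layer)
  }
})

test_that("the SPP tail adds no parameters beyond the baseline builder", {
  m1 <- build_model(tiny_cfg("SPP"))
  m2 <- build_model(tiny_cfg("SPP", seed = 2))
  expect_equal(profile_network(m1)$params, profile_network(m2)$params)
})

test_that("forward on zeros yields finite outputs at all three strides", {
  m <- build_model(tiny_cfg("LAAM"))
  out <- seg_forward(m, feature_map(array(0, dim = c(3, 64, 64, 1))))
  expect_equal(dim(out$p3)[2:3], c(8, 8))
  expect_equal(dim(out$p4)[2:3], c(4, 4))
  expect_equal(dim(out$p5)[2:3], c(2, 2))
  expect_equal(dim(out$proto)[1:3], c(32, 16, 16))
  for (o in out[1:4]) expect_true(all(is.finite(o)))
})

test_that("a scalar loss reaches the first backbone conv for every variant", {
  for (v in c("SPP", "ASPP", "LAAM")) {
    m <- build_model(tiny_cfg(v, size = 32))
    x <- feature_map(array(rnorm(3 * 32 * 32) * 0.1, dim = c(3, 32, 32, 1)))
    out <- seg_forward(m, x, train = TRUE)
    g <- lapply(out[1:4], function(o) array(1e-3, dim = dim(o)))
    names(g) <- c("p3", "p4", "p5", "proto")
    zero_grads(m)
    dx <- seg_backward(m, g)
    stem_grad <- nn_params(m$L0)[[1]]$grad
    expect_gt(sum(abs(stem_grad)), 0, label = v)
    expect_true(all(is.finite(dx)))
  }
})

test_that("fixed seed makes model construction and forward bit-identical", {
  m1 <- build_model(tiny_cfg("LAAM", seed = 5))
  m2 <- build_model(tiny_cfg("LAAM", seed = 5))
  x <- fixture_fm(3, 64, 64, 1, seed = 6)
  expect_identical(seg_forward(m1, x)$p5, seg_forward(m2, x)$p5)
})

test_that("greedy NMS: duplicate removal and threshold boundary", {
  b <- matrix(c(10, 10, 50, 50,
                10, 10, 50, 50,
                60, 60, 90, 90), ncol = 4, byrow = TRUE)
  s <- c(0.9, 0.8, 0.7)
  expect_equal(sort(nms_greedy(b, s, 0.5)), c(1, 3))  # exact duplicate dies
  expect_equal(sort(nms_greedy(b, s, 1.0)), c(1, 2, 3))  # no suppression
  expect_equal(nms_greedy(b[1, , drop = FALSE], 0.5, 0.5), 1)
})

test_that("prediction rejects unnormalized input and filters by confidence", {
  m <- build_model(tiny_cfg("SPP", size = 32))
  bad <- array(runif(3 * 32 * 32) * 255, dim = c(3, 32, 32, 1))
  expect_error(forward_predict(m, bad), "normalized")
  ok <- bad / 255
  preds <- forward_predict(m, ok, conf_thr = 0.99)
  expect_equal(nrow(preds[[1]]$boxes), 0)  # untrained, near-prior confidences
})

test_that("box IoU matrix agrees with hand geometry", {
  a <- matrix(c(0, 0, 2, 2), 1)
  b <- matrix(c(1, 1, 3, 3,   2, 2, 4, 4), 2, byrow = TRUE)
  iou <- box_iou_xyxy(a, b)
  expect_equal(iou[1, 1], 1 / 7)
  expect_equal(iou[1, 2], 0)
})
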