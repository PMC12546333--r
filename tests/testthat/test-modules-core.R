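# Tail-module family: shape preservation, attention ranges, the depthwise
# parameter economy, the ablation-grid algebra and the complexity ordering.

small_spec <- function(variant, c = 16L)
  module_spec(variant, c, c, channel_reduction = 4L, branch_width_ratio = 0.5)

test_that("every variant preserves spatial shape across sizes", {
  set.seed(10)
  for (v in VARIANT_NAMES) {
    mod <- build_variant(small_spec(v))
    for (hw in c(8L, 16L, 20L, 32L)) {
      y <- nn_forward(mod, fixture_fm(16, hw, hw, 1, seed = hw))
      expect_equal(dim(y), c(16, hw, hw, 1), label = paste(v, hw))
      expect_true(all(is.finite(y)))
    }
  }
})

test_that("depthwise separable conv: shapes, identity case, parameter economy", {
  set.seed(11)
  l <- ds_conv(8, 12, 3, dilation = 6)
  expect_equal(dim(nn_forward(l, fixture_fm(8, 20, 20))), c(12, 20, 20, 1))

  # kernel 1, identity pointwise, zero bias, no norm: output = relu(relu(x)) = relu(x)
  li <- ds_conv(4, 4, 1, dilation = 1, norm = FALSE, act = "relu")
  convs <- Filter(function(z) inherits(z, "conv2d"), nn_leaves(li))
  convs[[1]]$W$value[] <- 1                 # depthwise 1x1 identity
  convs[[1]]$b$value[] <- 0
  convs[[2]]$W$value[] <- diag(4)           # pointwise identity
  convs[[2]]$b$value[] <- 0
  x <- fixture_fm(4, 5, 5)
  expect_equal(as.numeric(nn_forward(li, x)), pmax(as.numeric(x), 0))

  # closed-form parameter count for in=512, out=256, k=3
  lw <- ds_conv(512, 256, 3)
  kernel_params <- sum(vapply(Filter(function(z) inherits(z, "conv2d"),
                                     nn_leaves(lw)),
                              function(z) length(z$W$value), numeric(1)))
  expect_equal(kernel_params, 512 * 9 + 512 * 256)
  expect_lt(kernel_params / (512 * 256 * 9), 0.12)
})

test_that("channel attention weights are sigmoid-gated and well shaped", {
  set.seed(12)
  for (ctor in list(channel_attention_standard, channel_attention_simplified)) {
    att <- ctor(32, 4)
    w <- nn_forward(att, fixture_fm(32, 20, 20, 2))
    expect_equal(dim(w), c(32, 1, 1, 2))
    expect_true(all(w > 0 & w < 1))
  }
  expect_error(channel_attention_standard(8, 16), "exceeds")
  expect_error(channel_attention_standard(10, 3), "divide")
})

test_that("channel attention is permutation-equivariant and spatially invariant", {
  set.seed(13)
  att <- channel_attention_simplified(8, 2)
  x <- fixture_fm(8, 6, 6, 1)
  w <- nn_forward(att, x)
  # spatial permutation leaves GAP untouched
  xp <- unclass(x)
  perm <- sample(36)
  xp2 <- array(0, dim = dim(xp))
  xp2[, , , 1] <- array(matrix(xp, 8)[, perm], dim = c(8, 6, 6))
  expect_equal(as.numeric(nn_forward(att, feature_map(xp2))), as.numeric(w))

  # channel permutation of a standard attention with permuted weights
  att2 <- channel_attention_standard(8, 2)
  x2 <- fixture_fm(8, 5, 5)
  w2 <- nn_forward(att2, x2)
  cp <- c(3, 1, 2, 5, 4, 8, 6, 7)
  att3 <- channel_attention_standard(8, 2)
  att3$W1$value <- att2$W1$value[cp, ]
  att3$b1$value <- att2$b1$value
  att3$W2$value <- att2$W2$value[, cp]
  att3$b2$value <- att2$b2$value[cp]
  xq <- feature_map(unclass(x2)[cp, , , , drop = FALSE])
  expect_equal(as.numeric(nn_forward(att3, xq)), as.numeric(w2)[cp],
               tolerance = 1e-12)
})

test_that("zeroed attention weights give uniform 0.5 gates", {
  att <- channel_attention_standard(8, 2)
  att$W1$value[] <- 0; att$W2$value[] <- 0
  att$b1$value[] <- 0; att$b2$value[] <- 0
  w <- nn_forward(att, fixture_fm(8, 4, 4))
  expect_equal(as.numeric(w), rep(0.5, 8))

  sp <- spatial_attention_simplified()
  sp$conv$W$value[] <- 0; sp$conv$b$value[] <- 0
  ws <- nn_forward(sp, feature_map(array(0, dim = c(8, 4, 4, 1))))
  expect_equal(as.numeric(ws), rep(0.5, 16))
})

test_that("simplified channel logit is monotone under nonnegative weights", {
  set.seed(14)
  att <- channel_attention_simplified(8, 2)
  att$W1$value <- abs(att$W1$value)
  att$W2$value <- abs(att$W2$value)
  x <- feature_map(abs(rnorm(8 * 5 * 5)), 8, 5, 5)
  w1 <- nn_forward(att, x)
  x2 <- unclass(x); x2[3, , , ] <- 2 * x2[3, , , ]
  w2 <- nn_forward(att, feature_map(x2))
  expect_gte(w2[3, 1, 1, 1], w1[3, 1, 1, 1])
})

test_that("spatial attention: shapes, ranges, constancy, MAC advantage", {
  set.seed(15)
  std <- spatial_attention_standard()
  sim <- spatial_attention_simplified()
  x <- fixture_fm(16, 20, 20)
  for (att in list(std, sim)) {
    w <- nn_forward(att, x)
    expect_equal(dim(w), c(1, 20, 20, 1))
    expect_true(all(w > 0 & w < 1))
  }
  # spatially constant input -> constant weight map away from the border
  # (the 7x7 convolution's zero padding perturbs a 3-pixel rim)
  xc <- feature_map(array(rep(rnorm(16), 400), dim = c(16, 20, 20, 1)))
  wc <- nn_forward(std, xc)
  expect_lt(diff(range(wc[1, 4:17, 4:17, 1])), 1e-12)
  # single-channel input: mean and max maps coincide with the channel
  x1 <- fixture_fm(1, 6, 6)
  cp <- laamseg:::channel_pool(unclass(x1))
  expect_equal(cp$pooled[1, , , 1], cp$pooled[2, , , 1])
  # per-position MACs: 1x1 on 2 pooled channels vs 7x7 on 2 channels
  m_simple <- count_conv_macs(2, 1, 1, 20, 20)
  m_std <- count_conv_macs(2, 1, 7, 20, 20)
  expect_lt(m_simple, m_std)
})

test_that("attention gating never increases activation magnitude", {
  set.seed(16)
  for (ctor in list(function() cbam_standard(16, 4),
                    function() cbam_enhanced(16, 4))) {
    blk <- ctor()
    x <- fixture_fm(16, 10, 10, 2)
    y <- nn_forward(blk, x)
    expect_true(all(abs(y) <= abs(x) + 1e-12))
  }
})

test_that("ablation algebra: removing residuals reproduces the ablated variants", {
  set.seed(17)
  x <- fixture_fm(16, 12, 12, 2)

  laam <- build_variant(small_spec("LAAM"))
  llaam <- build_variant(small_spec("LLAAM"))
  # share every common submodule weight-for-weight
  st <- get_weights(laam)
  n_llaam <- length(get_weights(llaam)$weights)
  set_weights(llaam, list(weights = st$weights[seq_len(n_llaam)],
                          bn_stats = st$bn_stats[
                            seq_len(length(get_weights(llaam)$bn_stats))]))
  y_laam <- nn_forward(laam, x)
  y_llaam <- nn_forward(llaam, x)
  expect_identical(as.numeric(laam$pre_residual), as.numeric(y_llaam))
  expect_gt(max(abs(y_laam - y_llaam)), 0)  # the residual path does act

  apcm <- build_variant(small_spec("APCM"))
  lapcm <- build_variant(small_spec("LAPCM"))
  st2 <- get_weights(apcm)
  set_weights(lapcm, st2)
  y_apcm <- nn_forward(apcm, x)
  y_lapcm <- nn_forward(lapcm, x)
  expect_identical(as.numeric(apcm$pre_residual), as.numeric(y_lapcm))
  expect_identical(as.numeric(y_apcm), as.numeric(y_lapcm + unclass(x)))

  # LAAM minus the whole attention branch is the lightweight pyramid alone
  laspp <- build_variant(small_spec("LASPP"))
  st_l <- get_weights(laspp)
  n_shared <- length(st_l$weights)
  set_weights(laspp, list(weights = st$weights[seq_len(n_shared)],
                          bn_stats = st$bn_stats[
                            seq_len(length(st_l$bn_stats))]))
  y_laspp <- nn_forward(laspp, x)
  y_aspp_only <- nn_forward(laam$aspp, x)
  expect_identical(as.numeric(y_laspp), as.numeric(y_aspp_only))
})

test_that("lightweight pyramid undercuts the standard pyramid in MACs", {
  spec_s <- module_spec("ASPP", 512, 512)
  spec_l <- module_spec("LASPP", 512, 512)
  set.seed(18)
  m_s <- profile_network(aspp_standard(spec_s), c(512, 20, 20))
  m_l <- profile_network(aspp_lightweight(spec_l), c(512, 20, 20))
  expect_lt(m_l$macs, m_s$macs)
})

test_that("standard pyramid structure: branch count and constant pooling", {
  set.seed(19)
  spec <- small_spec("ASPP")
  blk <- aspp_standard(spec)
  expect_equal(blk$nb, 4L)  # 1x1, two dilations, global pool
  # concatenation width before fusion
  expect_equal(blk$fuse$layers[[1]]$in_c, 4L * blk$b)
  # constant input: the global-pool branch is spatially constant pre-fusion
  xc <- feature_map(array(2, dim = c(16, 8, 8, 1)))
  g <- laamseg:::gap_forward(unclass(xc))
  gb <- nn_forward(blk$brg, feature_map(g))
  expect_equal(length(unique(as.numeric(gb))), blk$b)
  expect_error(module_spec("ASPP", 16, dilation_rates = 6L), "dilation")
})

test_that("zero input with zero biases yields zero pre-activation pyramid output", {
  set.seed(20)
  blk <- aspp_lightweight(small_spec("LASPP"))
  # bn shifts are zero by construction; SiLU(0) = 0, so output is exactly 0
  x <- feature_map(array(0, dim = c(16, 8, 8, 1)))
  expect_true(all(nn_forward(blk, x) == 0))
})

test_that("variant registry maps names to compositions and flags unknowns", {
  set.seed(21)
  laam <- build_variant("LAAM", 16, channel_reduction = 4)
  expect_s3_class(laam$attn, "attn_enhanced")
  expect_false(is.null(laam$proj))
  laspp <- build_variant("LASPP", 16, channel_reduction = 4)
  expect_null(laspp$attn)
  expect_null(laspp$proj)
  expect_error(build_variant("CBAMX", 16), "valid names")
  expect_error(module_spec("LAAM", 16, residual = "none"), "projected_sum")
  # SPP has no weights beyond its two fusion conv blocks
  spp <- build_variant("SPP", 16)
  expect_equal(length(nn_params(spp)),
               length(nn_params(spp$aspp$cv1)) + length(nn_params(spp$aspp$cv2)))
})

test_that("module spec round-trips through YAML", {
  sp <- module_spec("LAAM", 512, 512, channel_reduction = 8)
  sp2 <- module_spec_from_yaml(module_spec_yaml(sp))
  expect_equal(sp[names(sp) != "branch_width_ratio"],
               sp2[names(sp2) != "branch_width_ratio"])
  expect_equal(sp$branch_width_ratio, sp2$branch_width_ratio)
})

test_that("fixed seed gives bit-identical builds and forwards", {
  x <- fixture_fm(16, 8, 8)
  set.seed(99); a <- build_variant(small_spec("LAAM"))
  set.seed(99); b <- build_variant(small_spec("LAAM"))
  expect_identical(as.numeric(nn_forward(a, x)), as.numeric(nn_forward(b, x)))
})

test_that("LAAM keeps gradient flow through the residual when attention saturates", {
  set.seed(22)
  laam <- build_variant(small_spec("LAAM"))
  # saturate both gates towards 0 via hugely negative attention parameters
  laam$attn$chan$W2$value[] <- -50
  laam$attn$spat$conv$b$value[] <- -50
  x <- fixture_fm(16, 8, 8)
  y <- nn_forward(laam, x, train = TRUE)
  dx <- nn_backward(laam, array(1, dim = dim(y)))
  expect_gt(max(abs(dx)), 0)
})
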