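# Phantom generator: determinism, label statistics, label/mask consistency,
# letterboxing, YOLO-format serialization, k-fold splitting.

test_that("generation is bit-identical under a fixed seed", {
  p <- phantom_params(image_size = 96, n_images = 2, seed = 3)
  a <- generate_phantom(p, 0)
  b <- generate_phantom(p, 0)
  expect_identical(a$image, b$image)
  expect_identical(a$labels[[1]]$polygon, b$labels[[1]]$polygon)
  cc <- generate_phantom(p, 1)
  expect_false(identical(a$image, cc$image))
})

test_that("label geometry stays inside the configured ranges", {
  p <- phantom_params(image_size = 64, n_images = 200, noise_sigma = 0,
                      seed = 5)
  bb <- vapply(seq_len(200) - 1L,
               function(i) generate_phantom(p, i)$labels[[1]]$bbox,
               numeric(4))
  expect_true(all(bb[1, ] >= 0.2 & bb[1, ] <= 0.8))
  expect_true(all(bb[2, ] >= 0.2 & bb[2, ] <= 0.6))
  expect_true(all(bb[3, ] >= 0.2 & bb[3, ] <= 0.6))
  expect_true(all(bb[4, ] >= 0.2 & bb[4, ] <= 0.6))
})

test_that("stored polygon and stored mask agree (IoU >= 0.98)", {
  p <- phantom_params(image_size = 128, n_images = 10, seed = 6)
  for (i in 0:9) {
    lb <- generate_phantom(p, i)$labels[[1]]
    rp <- rasterize_polygon(lb$polygon, 128, 128)
    expect_gte(sum(rp & lb$mask) / sum(rp | lb$mask), 0.98)
  }
})

test_that("noise-free tumors are recoverable by plain thresholding", {
  p <- phantom_params(image_size = 160, n_images = 6, noise_sigma = 0,
                      contrast = 1, seed = 8)
  for (i in 0:5) {
    g <- generate_phantom(p, i)
    lb <- g$labels[[1]]
    level <- 131 + if (lb$class_id == 0) 34 else 104
    thr <- g$image > (131 + level) / 2
    # the glioma surrogate's rim is diffuse by design (blur sigma = S/320),
    # so its halfway contour deviates from the mask by a sub-pixel rim; the
    # sharp-rim meningioma surrogate recovers near-exactly
    expect_gt(sum(thr & lb$mask) / sum(thr | lb$mask),
              if (lb$class_id == 0) 0.95 else 0.99)
  }
})

test_that("pixel values stay in [0,255] and both classes appear", {
  p <- phantom_params(image_size = 64, n_images = 20, seed = 9)
  cls <- integer(0)
  for (i in 0:19) {
    g <- generate_phantom(p, i)
    expect_true(all(g$image >= 0 & g$image <= 255))
    cls <- c(cls, g$labels[[1]]$class_id)
  }
  expect_setequal(unique(cls), c(0L, 1L))
})

test_that("letterboxing normalizes values and transforms labels consistently", {
  p <- phantom_params(image_size = 96, n_images = 1, seed = 10)
  g <- generate_phantom(p, 0)
  # square input: geometry unchanged, values / 255
  pp <- preprocess(g$image, 96, g$labels)
  expect_equal(dim(pp$x), c(3, 96, 96, 1))
  expect_equal(pp$x[1, 10, 20, 1], g$image[10, 20] / 255)
  expect_equal(pp$labels[[1]]$bbox, g$labels[[1]]$bbox, tolerance = 1e-12)
  expect_lte(max(pp$x), 1); expect_gte(min(pp$x), 0)
  # 2:1 aspect: equal top/bottom pads; a centered point stays centered
  wide <- g$image[seq(1, 96, by = 2), ]      # 48 x 96
  sq <- cbind(c(0.45, 0.55, 0.55, 0.45), c(0.45, 0.45, 0.55, 0.55))
  lab <- instance_label(0L, sq, mask_size = 64)
  pp2 <- preprocess(wide, 96, list(lab))
  expect_equal(pp2$meta$top, (96 - 48) / 2)
  expect_equal(as.numeric(pp2$labels[[1]]$bbox[1:2]), c(0.5, 0.5))
  expect_equal(as.numeric(pp2$labels[[1]]$bbox[3:4]), c(0.1, 0.05))
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "zero-area")
})

test_that("datasets round-trip through the YOLO text layout", {
  p <- phantom_params(image_size = 64, n_images = 2, seed = 11)
  ds <- generate_dataset(p)
  dir <- withr::local_tempdir()
  write_dataset(ds$images, ds$labels, dir)
  expect_true(file.exists(file.path(dir, "data.yaml")))
  lab_file <- file.path(dir, "labels", "img_00000.txt")
  lines <- readLines(lab_file)
  expect_length(lines, 1)
  expect_equal(strsplit(lines, " ")[[1]][1],
               as.character(ds$labels[[1]][[1]]$class_id))
  back <- read_labels(lab_file)
  expect_equal(back[[1]]$polygon, ds$labels[[1]][[1]]$polygon,
               tolerance = 1e-6)
  # empty-instance image gets an empty but present label file
  write_dataset(list(ds$images[[1]]), list(list()), file.path(dir, "sub"))
  ef <- file.path(dir, "sub", "labels", "img_00000.txt")
  expect_true(file.exists(ef))
  expect_length(readLines(ef), 0)
  # loader reads the whole set back
  ds2 <- load_dataset(dir)
  expect_length(ds2$images, 2)
  expect_equal(dim(ds2$images[[1]]), c(64, 64))
})

test_that("k-fold splits partition the ids exactly", {
  f <- split_kfold(3000, 5, seed = 1)
  expect_length(f, 5)
  for (fd in f) {
    expect_length(fd$val, 600)
    expect_length(fd$train, 2400)
    expect_length(intersect(fd$train, fd$val), 0)
  }
  allval <- unlist(lapply(f, `[[`, "val"))
  expect_setequal(allval, 1:3000)
  expect_identical(split_kfold(10, 5, 7), split_kfold(10, 5, 7))
  expect_error(split_kfold(3, 5), "exceeds")
  expect_error(split_kfold(10, 1), ">= 2")
})
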