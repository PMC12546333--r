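# Synthetic axial brain-MRI phantoms. Each image holds an elliptical "brain"
# on a dark background plus one tumor-like blob of one of two surrogate
# classes: class 0 (glioma surrogate) is an irregular star-convex region with
# a blurred, low-contrast rim; class 1 (meningioma surrogate) is a compact
# ellipse with a sharp, high-contrast rim. Tumor centers are drawn from
# x in [0.2, 0.8], y in [0.2, 0.6] and normalized sizes from [0.2, 0.6],
# matching the annotation statistics the pipeline is designed around.

#' Phantom generator parameters
#'
#' @param image_size square image size in pixels.
#' @param n_images number of images the dataset will hold.
#' @param class_mix probability that an instance is class 1
#'   (meningioma surrogate).
#' @param center_range_x,center_range_y,size_range normalized ranges for the
#'   tumor center and bounding-box width/height.
#' @param noise_sigma Gaussian pixel noise s.d. (0-255 scale).
#' @param contrast multiplies the tumor intensity increment.
#' @param seed RNG seed; image `index` is deterministic given (seed, index).
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(image_size = 640L, n_images = 64L, class_mix = 0.5,
                           center_range_x = c(0.2, 0.8),
                           center_range_y = c(0.2, 0.6),
                           size_range = c(0.2, 0.6),
                           noise_sigma = 6, contrast = 1, seed = 0L) {
  stopifnot(noise_sigma >= 0, class_mix >= 0, class_mix <= 1)
  rng_ok <- function(r) all(r >= 0 & r <= 1) && r[1] <= r[2]
  if (!rng_ok(center_range_x) || !rng_ok(center_range_y) || !rng_ok(size_range))
    stop("phantom_params: ranges must lie within [0,1]")
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images), class_mix = class_mix,
                 center_range_x = center_range_x,
                 center_range_y = center_range_y, size_range = size_range,
                 noise_sigma = noise_sigma, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

# tumor geometry: star-convex radial profile r(theta)/R = 1 + sum a_k cos(k
# theta + phi_k); class 0 uses strong harmonics (irregular), class 1 weak ones
sample_tumor_geometry <- function(params) {
  class_id <- as.integer(stats::runif(1) < params$class_mix)
  cx <- runif1(params$center_range_x)
  cy <- runif1(params$center_range_y)
  w <- runif1(params$size_range)
  h <- runif1(params$size_range)
  # keep the box inside the image (labels must stay in [0,1])
  w <- min(w, 2 * min(cx, 1 - cx) - 0.02)
  h <- min(h, 2 * min(cy, 1 - cy) - 0.02)
  w <- max(w, params$size_range[1])
  h <- max(h, params$size_range[1])
  if (class_id == 0L) {
    k <- 3:6
    amp <- stats::runif(length(k), 0.04, 0.13)
  } else {
    k <- 2:3
    amp <- stats::runif(length(k), 0.00, 0.03)
  }
  phase <- stats::runif(length(k), 0, 2 * pi)
  list(class_id = class_id, cx = cx, cy = cy, w = w, h = h,
       k = k, amp = amp, phase = phase)
}

# Affine normalization of the star shape so that its axis-aligned bounding
# box is exactly (cx +- w/2, cy +- h/2); polygon and raster mask share it.
tumor_shape <- function(geo) {
  th <- seq(0, 2 * pi, length.out = 1024L + 1L)[-1]
  r <- 1 + rowSums(vapply(seq_along(geo$k),
                          function(i) geo$amp[i] * cos(geo$k[i] * th + geo$phase[i]),
                          numeric(length(th))))
  r <- pmax(r, 0.2)
  ux <- r * cos(th); uy <- r * sin(th)
  list(th = th, ux = ux, uy = uy,
       sx = geo$w / (max(ux) - min(ux)), midx = (max(ux) + min(ux)) / 2,
       sy = geo$h / (max(uy) - min(uy)), midy = (max(uy) + min(uy)) / 2)
}

tumor_polygon <- function(geo, n_vertices = 72L) {
  sh <- tumor_shape(geo)
  sel <- round(seq(1L, length(sh$th),
                   length.out = n_vertices + 1L))[-(n_vertices + 1L)]
  # always include the four extreme boundary points, so the polygon's
  # bounding box equals the sampled (cx, cy, w, h) exactly
  sel <- sort(unique(c(sel, which.min(sh$ux), which.max(sh$ux),
                       which.min(sh$uy), which.max(sh$uy))))
  cbind(pmin(pmax(geo$cx + (sh$ux[sel] - sh$midx) * sh$sx, 0), 1),
        pmin(pmax(geo$cy + (sh$uy[sel] - sh$midy) * sh$sy, 0), 1))
}

# exact inside test on the pixel grid using the same radial profile
tumor_mask <- function(geo, size) {
  sh <- tumor_shape(geo)
  xs <- (seq_len(size) - 0.5) / size
  gx <- matrix(rep(xs, each = size), size, size)   # columns = x
  gy <- matrix(rep(xs, size), size, size)          # rows = y
  ux <- (gx - geo$cx) / sh$sx + sh$midx
  uy <- (gy - geo$cy) / sh$sy + sh$midy
  th <- atan2(uy, ux)
  rr <- sqrt(ux^2 + uy^2)
  rprof <- 1
  for (i in seq_along(geo$k))
    rprof <- rprof + geo$amp[i] * cos(geo$k[i] * th + geo$phase[i])
  rr <= pmax(rprof, 0.2)
}

#' Generate one phantom image with its instance label
#'
#' Deterministic given `(params$seed, index)`.
#'
#' @param params a [phantom_params()].
#' @param index image index, `0 <= index < n_images`.
#' @return list with `image` (matrix, values in \[0, 255\]) and `labels`
#'   (list of [instance_label()]s; length 1).
#' @export
generate_phantom <- function(params, index) {
  if (index >= params$n_images) stop("generate_phantom: index out of range")
  set.seed((params$seed %% 1000003L) * 2017L + as.integer(index))
  S <- params$image_size
  xs <- (seq_len(S) - 0.5) / S
  gx <- matrix(rep(xs, each = S), S, S)
  gy <- matrix(rep(xs, S), S, S)
  # brain ellipse with mild low-frequency texture
  ex <- (gx - 0.5) / 0.42; ey <- (gy - 0.52) / 0.46
  brain <- ex^2 + ey^2 <= 1
  base <- 115 + 10 * exp(-((ex^2 + ey^2) * 1.5))
  tex <- 6 * cos(2 * pi * (stats::runif(1) + 1.5 * gx + 0.8 * gy)) *
    cos(2 * pi * (stats::runif(1) + 0.7 * gx - 1.6 * gy))
  img <- matrix(8, S, S)
  img[brain] <- (base + tex)[brain]
  geo <- sample_tumor_geometry(params)
  if (geo$w / 2 > 0.42 || geo$h / 2 > 0.46)
    warning("generate_phantom: tumor size clipped to the brain extent")
  mask <- tumor_mask(geo, S)
  # absolute tumor level: low contrast for the glioma surrogate, high for the
  # meningioma surrogate; the rim blur differs likewise (diffuse vs sharp)
  level <- 131 + (if (geo$class_id == 0L) 34 else 104) * params$contrast
  bump <- matrix(0, S, S)
  bump[mask] <- level - img[mask]
  sigma <- if (geo$class_id == 0L) S / 320 else S / 1280
  bump <- ebimage_blur(bump, sigma)
  img <- img + bump
  if (params$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(S * S, 0, params$noise_sigma), S, S)
  img <- pmin(pmax(img, 0), 255)
  poly <- tumor_polygon(geo)
  lab <- instance_label(geo$class_id, poly, mask = mask)
  list(image = img, labels = list(lab))
}

# EBImage works in (x, y) order; our matrices are (row = y, col = x)
ebimage_blur <- function(mat, sigma) {
  if (sigma <= 0.25) return(mat)
  t(as.matrix(EBImage::gblur(EBImage::Image(t(mat)), sigma = sigma)))
}

#' Letterbox-resize an image to a square and normalize to \[0, 1\]
#'
#' The image is scaled preserving aspect ratio, centered on a gray canvas
#' (114/255), and divided by 255. Label coordinates are transformed
#' consistently.
#'
#' @param image matrix (grayscale) or H x W x 3 array, values in \[0, 255\].
#' @param size target square size.
#' @param labels optional list of [instance_label()]s to transform.
#' @return list with `x` (feature map (3, size, size, 1)), `labels`
#'   (transformed), and `meta` (scale and pixel offsets).
#' @export
preprocess <- function(image, size = 640L, labels = NULL) {
  if (length(dim(image)) == 3L) image <- image[, , 1]
  h <- nrow(image); w <- ncol(image)
  if (h == 0 || w == 0) stop("preprocess: zero-area image")
  r <- min(size / h, size / w)
  nh <- round(h * r); nw <- round(w * r)
  resized <- if (nh == h && nw == w) image else
    t(as.matrix(EBImage::resize(EBImage::Image(t(image)), w = nw, h = nh)))
  top <- (size - nh) %/% 2L
  left <- (size - nw) %/% 2L
  canvas <- matrix(114, size, size)
  canvas[(top + 1):(top + nh), (left + 1):(left + nw)] <- resized
  x <- array(0, dim = c(3L, size, size, 1L))
  for (ci in 1:3) x[ci, , , 1] <- canvas / 255
  newlab <- NULL
  if (!is.null(labels)) {
    newlab <- lapply(labels, function(lb) {
      poly <- cbind((lb$polygon[, 1] * w * r + left) / size,
                    (lb$polygon[, 2] * h * r + top) / size)
      instance_label(lb$class_id, poly, mask_size = size)
    })
  }
  list(x = as_fm(x), labels = newlab,
       meta = list(scale = r, top = top, left = left))
}

#' Write a dataset to disk in YOLO segmentation layout
#'
#' PNG images under `images/`, one label text file per image under `labels/`
#' (`class x1 y1 x2 y2 ...`, normalized polygon, one instance per line; empty
#' file for empty images), plus a `data.yaml` manifest.
#'
#' @param images list of matrices (0-255).
#' @param labels list of lists of [instance_label()]s.
#' @param dir output directory.
#' @param class_names character vector of class names.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(images, labels, dir,
                          class_names = c("glioma", "meningioma")) {
  img_dir <- file.path(dir, "images")
  lab_dir <- file.path(dir, "labels")
  for (d in c(img_dir, lab_dir))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("write_dataset: cannot create directory ", d)
  for (i in seq_along(images)) {
    stem <- sprintf("img_%05d", i - 1L)
    ip <- file.path(img_dir, paste0(stem, ".png"))
    ok <- tryCatch({
      png::writePNG(images[[i]] / 255, ip)
      TRUE
    }, error = function(e) stop("write_dataset: failed writing ", ip, ": ",
                                conditionMessage(e)))
    lines <- vapply(labels[[i]], function(lb)
      paste(lb$class_id,
            paste(sprintf("%.6f", t(lb$polygon)), collapse = " ")),
      character(1))
    writeLines(lines, file.path(lab_dir, paste0(stem, ".txt")))
  }
  manifest <- file.path(dir, "data.yaml")
  yaml::write_yaml(list(path = normalizePath(dir), images = "images",
                        labels = "labels", nc = length(class_names),
                        names = as.list(class_names)), manifest)
  invisible(manifest)
}

#' Read one YOLO segmentation label file
#' @param path label text file.
#' @param mask_size raster size for the reconstructed masks.
#' @return list of [instance_label()]s (possibly empty).
#' @export
read_labels <- function(path, mask_size = 160L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    instance_label(as.integer(v[1]),
                   matrix(v[-1], ncol = 2, byrow = TRUE),
                   mask_size = mask_size)
  })
}

#' Deterministic k-fold split
#'
#' Items are shuffled once by `seed` and divided into `k` equal subsets;
#' fold `i` uses subset `i` as validation and the rest as training. Folds are
#' disjoint and exhaustive.
#'
#' @param n_items number of items.
#' @param k number of folds (>= 2, <= n_items).
#' @param seed shuffle seed.
#' @return list of `k` lists with `train` and `val` integer id vectors.
#' @export
split_kfold <- function(n_items, k = 5L, seed = 0L) {
  if (k < 2L) stop("split_kfold: k must be >= 2")
  if (k > n_items) stop("split_kfold: k exceeds the number of items")
  set.seed(seed)
  ids <- sample.int(n_items)
  fold_of <- sort(rep(seq_len(k), length.out = n_items))
  lapply(seq_len(k), function(i) {
    val <- ids[fold_of == i]
    list(train = sort(ids[fold_of != i]), val = sort(val))
  })
}

#' Generate a full phantom dataset in memory
#' @param params a [phantom_params()].
#' @return list with `images` and `labels` (parallel lists).
#' @export
generate_dataset <- function(params) {
  out <- lapply(seq_len(params$n_images) - 1L,
                function(i) generate_phantom(params, i))
  list(images = lapply(out, `[[`, "image"),
       labels = lapply(out, `[[`, "labels"))
}
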