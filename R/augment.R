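#' Real-time data-augmentation configuration
#'
#' Label-preserving transforms applied to each training image independently
#' every epoch: a deterministic multiplicative intensity rescale, a rotation
#' drawn uniformly from `±rotation_range`, a shear from `±shear_range`
#' (degrees), a zoom from `[1 - zoom_range, 1 + zoom_range]`, and, when
#' enabled, a horizontal flip with probability 0.5. Out-of-frame pixels after
#' the affine warp are filled by clamping to the nearest edge pixel, which
#' avoids introducing artificial dark corners that would mimic the disrupted
#' phenotype. The rasters handled by this package are already normalised to
#' `[0, 1]`, so `rescale` defaults to 1; use 1/255 when feeding raw 8-bit
#' integer images.
#'
#' @param rotation_range max absolute rotation, degrees
#' @param rescale multiplicative intensity factor (> 0), applied
#'   deterministically
#' @param shear_range max absolute shear angle, degrees
#' @param zoom_range max fractional zoom in/out
#' @param horizontal_flip enable random horizontal flips
#' @return list of class `"augmentation_config"`
#' @export
augmentation_config <- function(rotation_range = 40, rescale = 1,
                                shear_range = 0.2 * 180 / pi,
                                zoom_range = 0.2, horizontal_flip = TRUE) {
  if (rotation_range < 0 || shear_range < 0 || zoom_range < 0)
    stop("augmentation ranges must be non-negative")
  if (rescale <= 0) stop("rescale must be positive")
  if (zoom_range >= 1) stop("zoom_range must be below 1")
  structure(list(rotation_range = rotation_range, rescale = rescale,
                 shear_range = shear_range, shear_units = "degrees",
                 zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip)),
            class = "augmentation_config")
}

#' Apply one affine warp (rotation / shear / zoom / flip) to an image
#'
#' The transform is taken about the image centre; resampling is bilinear with
#' edge-clamped coordinates (nearest-edge fill). An identity transform
#' returns the input bit-for-bit.
#'
#' @param img numeric matrix in row = y, column = x convention
#' @param angle rotation in degrees (counter-clockwise)
#' @param shear shear angle in degrees (x displaced proportionally to y)
#' @param zoom isotropic scale factor (> 1 enlarges the object)
#' @param flip horizontal flip before the other transforms
#' @return warped matrix, same dimensions
#' @export
apply_affine <- function(img, angle = 0, shear = 0, zoom = 1, flip = FALSE) {
  h <- nrow(img); w <- ncol(img)
  if (angle == 0 && shear == 0 && zoom == 1 && !flip) return(img)
  th <- angle * pi / 180
  sh <- tan(shear * pi / 180)
  # forward map: flip -> shear -> zoom -> rotate; build the combined matrix
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(zoom, 0, 0, zoom), 2, 2)
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  Fm <- matrix(c(if (flip) -1 else 1, 0, 0, 1), 2, 2)
  A <- R %*% S %*% Sh %*% Fm
  Ainv <- solve(A)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - cy, h, w)
  # coordinates are (x, y) with y down; sample source position per output px
  sx <- Ainv[1, 1] * xs + Ainv[1, 2] * ys + cx
  sy <- Ainv[2, 1] * xs + Ainv[2, 2] * ys + cy
  sx <- pmin(pmax(sx, 1), w)
  sy <- pmin(pmax(sy, 1), h)
  x0 <- pmin(floor(sx), w - 1); y0 <- pmin(floor(sy), h - 1)
  fx <- sx - x0; fy <- sy - y0
  idx <- function(yy, xx) img[cbind(as.vector(yy), as.vector(xx))]
  v <- (1 - fx) * (1 - fy) * idx(y0, x0) +
       fx * (1 - fy) * idx(y0, x0 + 1) +
       (1 - fx) * fy * idx(y0 + 1, x0) +
       fx * fy * idx(y0 + 1, x0 + 1)
  matrix(v, h, w)
}

#' Augment a batch of images
#'
#' Each image receives independently drawn transform parameters; output
#' shapes equal input shapes and labels are untouched (the function never
#' sees them). Deterministic under `seed`. An empty batch returns an empty
#' batch.
#'
#' @param images list of numeric matrices (or `spheroid_image`s), all one
#'   shape
#' @param config an [augmentation_config()]
#' @param seed integer seed
#' @return list of matrices, same length and shapes
#' @export
augment_batch <- function(images, config = augmentation_config(), seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  if (length(images) == 0) return(list())
  pix <- lapply(images, function(im)
    if (inherits(im, "spheroid_image")) im$pixels else im)
  d <- dim(pix[[1]])
  for (p in pix)
    if (!identical(dim(p), d)) stop("images must share one raster shape")
  n <- length(pix)
  draws <- with_seed(seed, data.frame(
    angle = stats::runif(n, -config$rotation_range, config$rotation_range),
    shear = stats::runif(n, -config$shear_range, config$shear_range),
    zoom = stats::runif(n, 1 - config$zoom_range, 1 + config$zoom_range),
    flip = config$horizontal_flip & stats::runif(n) < 0.5
  ))
  lapply(seq_len(n), function(i) {
    out <- apply_affine(pix[[i]], draws$angle[i], draws$shear[i],
                        draws$zoom[i], draws$flip[i])
    if (config$rescale != 1) out <- out * config$rescale
    out
  })
}
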