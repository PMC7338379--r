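#' Segment the spheroid foreground
#'
#' Otsu threshold, optional morphological closing, connected-component
#' labelling (8-connectivity) and removal of tiny specks. The mask keeps all
#' surviving components — fragmented spheroids therefore yield
#' `n_components > 1`, which the morphometry baseline exploits. A blank image
#' (no foreground after thresholding) returns an empty mask flagged via
#' `empty`, not an error.
#'
#' @param image a `"spheroid_image"` or numeric matrix in `[0, 1]`
#' @param closing_size diameter (pixels) of the disc brush used for closing;
#'   0 disables
#' @param min_area components smaller than this many pixels are discarded
#' @param keep_largest keep only the largest component
#' @return list of class `"spheroid_mask"`: `mask` (logical matrix), `labels`
#'   (integer matrix), `n_components`, `empty`
#' @export
segment_spheroid <- function(image, closing_size = 5L, min_area = 16L,
                             keep_largest = FALSE) {
  px <- if (inherits(image, "spheroid_image")) image$pixels else image
  stopifnot(is.matrix(px))
  rng <- range(px)
  if (diff(rng) < 1e-8) {
    return(structure(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                          labels = matrix(0L, nrow(px), ncol(px)),
                          n_components = 0L, empty = TRUE),
                     class = "spheroid_mask"))
  }
  thr <- EBImage::otsu(EBImage::Image(px), range = rng)
  bw <- px > thr
  if (closing_size > 0) {
    brush <- EBImage::makeBrush(closing_size + (1 - closing_size %% 2), "disc")
    bw <- EBImage::closing(EBImage::Image(bw * 1), brush) > 0.5
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (keep_largest && length(keep) > 0) keep <- which.max(sizes)
  mask <- matrix(lab %in% keep & lab > 0, nrow(px), ncol(px))
  lab[!mask] <- 0L
  # relabel compactly
  if (length(keep) > 0) lab <- matrix(match(lab, keep, nomatch = 0L),
                                      nrow(px), ncol(px))
  structure(list(mask = mask, labels = lab,
                 n_components = length(keep), empty = length(keep) == 0L),
            class = "spheroid_mask")
}

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1), w)
  m[ri, ci, drop = FALSE]
}

sobel_magnitude <- function(px) {
  gx <- (shift_mat(px, -1, 1) + 2 * shift_mat(px, 0, 1) + shift_mat(px, 1, 1)) -
        (shift_mat(px, -1, -1) + 2 * shift_mat(px, 0, -1) + shift_mat(px, 1, -1))
  gy <- (shift_mat(px, 1, -1) + 2 * shift_mat(px, 1, 0) + shift_mat(px, 1, 1)) -
        (shift_mat(px, -1, -1) + 2 * shift_mat(px, -1, 0) + shift_mat(px, -1, 1))
  sqrt(gx^2 + gy^2) / 8  # normalise to intensity units per pixel
}

boundary_pixels <- function(mask) {
  inner <- shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
           shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  mask & !inner
}

hull_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  x <- pts[h, 2]; y <- pts[h, 1]
  n <- length(h)
  # shoelace; +perimeter/2 +1 (Pick-style) keeps discs near area/hull = 1
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  a + n / 2 + 1
}

#' Classical morphometric features of a segmented spheroid
#'
#' Computes projected foreground area, the equivalent circle radius, the
#' sphere-model volume in arbitrary units
#' (`volume_au = 4/3 * pi * equivalent_radius^3`), the mean Sobel gradient
#' magnitude over mask-boundary pixels (`edge_contrast`), the connected
#' component count, and solidity (area over convex-hull area). An empty mask
#' yields all-zero features with `empty = TRUE`.
#'
#' @param image a `"spheroid_image"` or numeric matrix
#' @param mask optional `"spheroid_mask"`; segmented from `image` if missing
#' @return list of class `"morph_features"`
#' @export
compute_features <- function(image, mask = NULL) {
  px <- if (inherits(image, "spheroid_image")) image$pixels else image
  if (is.null(mask)) mask <- segment_spheroid(px)
  stopifnot(inherits(mask, "spheroid_mask"))
  if (!identical(dim(mask$mask), dim(px)))
    stop("mask does not align with image")
  if (mask$empty) {
    return(structure(list(foreground_area = 0, equivalent_radius = 0,
                          volume_au = 0, edge_contrast = 0, n_components = 0L,
                          solidity = 0, empty = TRUE),
                     class = "morph_features"))
  }
  area <- sum(mask$mask)
  eq_r <- sqrt(area / pi)
  grad <- sobel_magnitude(px)
  bound <- boundary_pixels(mask$mask)
  structure(list(
    foreground_area = area,
    equivalent_radius = eq_r,
    volume_au = 4 / 3 * pi * eq_r^3,
    edge_contrast = mean(grad[bound]),
    n_components = mask$n_components,
    solidity = min(area / hull_area(mask$mask), 1),
    empty = FALSE
  ), class = "morph_features")
}

#' Feature table for a set of images
#'
#' @param images list of `"spheroid_image"`s
#' @return data frame keyed by `id` with one row of [compute_features()]
#'   output per image (plus `true_class` when known)
#' @export
morphometry_table <- function(images) {
  rows <- lapply(images, function(im) {
    f <- compute_features(im)
    data.frame(id = im$id, true_class = im$true_class,
               foreground_area = f$foreground_area,
               equivalent_radius = f$equivalent_radius,
               volume_au = f$volume_au, edge_contrast = f$edge_contrast,
               n_components = f$n_components, solidity = f$solidity)
  })
  do.call(rbind, rows)
}

#' Interpretable baseline: two cut-points on boundary edge contrast
#'
#' Orders the three viability classes by their mean edge contrast (cohesive
#' sharp-edged spheroids score highest) and grid-searches two thresholds that
#' maximise training accuracy. Serves as a sanity baseline proving the
#' synthetic classes carry learnable morphological signal without a neural
#' network.
#'
#' @param features data frame from [morphometry_table()] with `true_class`
#' @return list of class `"morph_baseline"` with thresholds and class order
#' @export
fit_morphometry_baseline <- function(features) {
  stopifnot(all(c("edge_contrast", "true_class") %in% names(features)))
  cls <- spheroid_classes()
  means <- vapply(cls, function(cl)
    mean(features$edge_contrast[features$true_class == cl]), numeric(1))
  ord <- cls[order(means, decreasing = TRUE)]  # high contrast first
  x <- features$edge_contrast
  cand <- sort(unique(x))
  cand <- c(min(x) - 1, (cand[-1] + cand[-length(cand)]) / 2, max(x) + 1)
  if (length(cand) > 400)
    cand <- cand[unique(round(seq(1, length(cand), length.out = 400)))]
  # below[i, k]: how many items of class ord[k] fall strictly below cand[i]
  below <- sapply(ord, function(cl)
    findInterval(cand, sort(x[features$true_class == cl]), left.open = TRUE))
  n_per <- vapply(ord, function(cl) sum(features$true_class == cl), numeric(1))
  best <- list(acc = -1, t_hi = Inf, t_lo = -Inf)
  for (i_hi in seq_along(cand)) {
    lo <- seq_len(i_hi)  # t_lo <= t_hi
    correct <- (n_per[1] - below[i_hi, 1]) +
               (below[i_hi, 2] - below[lo, 2]) + below[lo, 3]
    j <- which.max(correct)
    if (correct[j] > best$acc * nrow(features)) {
      best <- list(acc = correct[j] / nrow(features),
                   t_hi = cand[i_hi], t_lo = cand[lo[j]])
    }
  }
  structure(list(class_order = ord, t_hi = best$t_hi, t_lo = best$t_lo,
                 train_accuracy = best$acc),
            class = "morph_baseline")
}

#' @rdname fit_morphometry_baseline
#' @param baseline a fitted `"morph_baseline"`
#' @param new_features feature data frame to classify
#' @return character vector of predicted classes
#' @export
predict_morphometry_baseline <- function(baseline, new_features) {
  stopifnot(inherits(baseline, "morph_baseline"))
  x <- new_features$edge_contrast
  ifelse(x >= baseline$t_hi, baseline$class_order[1],
         ifelse(x >= baseline$t_lo, baseline$class_order[2],
                baseline$class_order[3]))
}
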