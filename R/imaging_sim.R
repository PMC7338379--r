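#' Configuration for a single synthetic spheroid micrograph
#'
#' Describes one brightfield-like rendering: a bright cohesive cell mass on a
#' dark droplet background. `fragmentation` is the single axis along which the
#' cytotoxic phenotype is expressed: at 0 the spheroid is one round, cohesive,
#' sharp-edged mass; towards 1 it splits into up to `n_fragments_max`
#' displaced blobs with increasingly irregular, blurred boundaries and
#' surrounding debris. Boundary blur grows with both `edge_softness` and
#' `fragmentation`, so the mean boundary gradient (see
#' [compute_features()]`$edge_contrast`) decreases monotonically along the
#' phenotype axis.
#'
#' @param image_height,image_width raster size in pixels
#' @param base_radius nominal spheroid radius in pixels; must be positive and
#'   at most half the smaller image dimension
#' @param radius_jitter fractional uniform jitter on the radius
#' @param fragmentation phenotype severity in `[0, 1]`
#' @param edge_softness Gaussian blur sigma (pixels) applied to the boundary
#' @param texture_noise_sd additive Gaussian intensity noise
#' @param background_level droplet background intensity in `[0, 1]`
#' @param vignette_strength radial droplet vignette, 0 disables
#' @param n_fragments_max maximum number of blobs at full fragmentation
#' @param debris_density density of small detached-cell speckle in `[0, 1]`
#' @param rng_seed integer seed; identical config + seed gives a
#'   bit-identical image
#' @return a validated list of class `"simulation_config"`
#' @export
simulation_config <- function(image_height = 400L, image_width = 320L,
                              base_radius = 80, radius_jitter = 0.08,
                              fragmentation = 0, edge_softness = 1,
                              texture_noise_sd = 0.04,
                              background_level = 0.08,
                              vignette_strength = 0.25,
                              n_fragments_max = 6L, debris_density = 0,
                              rng_seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              base_radius = base_radius, radius_jitter = radius_jitter,
              fragmentation = fragmentation, edge_softness = edge_softness,
              texture_noise_sd = texture_noise_sd,
              background_level = background_level,
              vignette_strength = vignette_strength,
              n_fragments_max = as.integer(n_fragments_max),
              debris_density = debris_density,
              rng_seed = as.integer(rng_seed))
  if (cfg$image_height < 8 || cfg$image_width < 8)
    stop("image dimensions must be positive (and at least 8 px)")
  if (cfg$fragmentation < 0 || cfg$fragmentation > 1)
    stop("fragmentation must lie in [0, 1]")
  if (cfg$edge_softness < 0) stop("edge_softness must be >= 0")
  if (cfg$base_radius <= 0 ||
      cfg$base_radius > min(cfg$image_height, cfg$image_width) / 2)
    stop("geometry error: base_radius must be positive and at most half the ",
         "smaller image dimension")
  if (cfg$n_fragments_max < 1) stop("n_fragments_max must be >= 1")
  if (cfg$debris_density < 0 || cfg$debris_density > 1)
    stop("debris_density must lie in [0, 1]")
  structure(cfg, class = "simulation_config")
}

new_spheroid_image <- function(pixels, id, true_class = "unlabeled",
                               provenance = "simulated", meta = list()) {
  structure(list(pixels = pixels, id = id, true_class = true_class,
                 provenance = provenance, meta = meta),
            class = "spheroid_image")
}

#' @export
print.spheroid_image <- function(x, ...) {
  cat("<spheroid_image ", x$id, ">: ", nrow(x$pixels), "x", ncol(x$pixels),
      ", class ", x$true_class, " (", x$provenance, ")\n", sep = "")
  invisible(x)
}

# Add one blob with a harmonically-perturbed boundary to `img` (max compose).
# Irregularity and interior dimming scale with `rough`.
render_blob <- function(img, cy, cx, radius, rough, intensity) {
  h <- nrow(img); w <- ncol(img)
  # random low-order harmonics deform the boundary
  ks <- 2:6
  amp <- stats::rnorm(length(ks), 0, (0.02 + 0.22 * rough) / sqrt(ks))
  phs <- stats::runif(length(ks), 0, 2 * pi)
  rmax <- radius * (1 + sum(abs(amp)) + 0.05)
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(h, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(w, ceiling(cx + rmax))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  r <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  rb <- radius
  bound <- rb * (1 + Reduce(`+`, lapply(seq_along(ks), function(q)
    amp[q] * cos(ks[q] * th + phs[q]))))
  inside <- r <= bound
  # gentle interior shading: slightly darker core, brighter rim
  shade <- intensity * (0.85 + 0.15 * pmin(r / pmax(bound, 1e-9), 1))
  patch <- img[ii, jj, drop = FALSE]
  img[ii, jj] <- pmax(patch, ifelse(inside, shade, patch))
  img
}

#' Render one synthetic spheroid micrograph
#'
#' @param config a [simulation_config()]
#' @param id image identifier carried into the result
#' @return a `"spheroid_image"` whose `pixels` matrix has the configured
#'   dimensions and values in `[0, 1]`
#' @examples
#' img <- render_spheroid(simulation_config(image_height = 96,
#'                                          image_width = 96,
#'                                          base_radius = 24))
#' range(img$pixels)
#' @export
render_spheroid <- function(config, id = "spheroid") {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$rng_seed, {
    h <- config$image_height; w <- config$image_width
    frag <- config$fragmentation
    r <- config$base_radius *
      (1 + stats::runif(1, -config$radius_jitter, config$radius_jitter))
    area <- pi * r^2

    n_blobs <- max(1L, 1L + as.integer(round(frag * (config$n_fragments_max - 1L))))
    # main blob keeps most of the mass; the remainder is split unevenly
    shares <- if (n_blobs == 1L) 1 else {
      rest <- stats::rexp(n_blobs - 1L)
      rest <- rest / sum(rest) * (0.45 * frag)
      c(1 - sum(rest), rest)
    }
    cy0 <- h / 2 + stats::runif(1, -0.05, 0.05) * h
    cx0 <- w / 2 + stats::runif(1, -0.05, 0.05) * w

    img <- matrix(config$background_level, h, w)
    for (b in seq_len(n_blobs)) {
      rb <- sqrt(shares[b] * area / pi)
      if (b == 1L) {
        cy <- cy0; cx <- cx0
      } else {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 0.6, 1.4) * frag * 1.1 * r
        cy <- cy0 + d * sin(ang); cx <- cx0 + d * cos(ang)
      }
      intensity <- 0.78 * (1 - 0.18 * frag * stats::runif(1))
      img <- render_blob(img, cy, cx, rb, rough = frag, intensity = intensity)
    }

    # detached-cell debris speckle around the mass
    n_debris <- as.integer(round(config$debris_density * 50))
    for (k in seq_len(n_debris)) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 0.3, 2.0) * r
      img <- render_blob(img, cy0 + d * sin(ang), cx0 + d * cos(ang),
                         stats::runif(1, 1.2, 3), rough = 0.5,
                         intensity = stats::runif(1, 0.25, 0.45))
    }

    # boundary blur: explicit softness plus the cohesion loss of the phenotype
    sigma <- config$edge_softness + 2.5 * frag
    if (sigma >= 0.3)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))

    if (config$texture_noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, config$texture_noise_sd), h, w)

    if (config$vignette_strength > 0) {
      dy <- matrix((seq_len(h) - h / 2) / (h / 2), h, w)
      dx <- matrix((seq_len(w) - w / 2) / (w / 2), h, w, byrow = TRUE)
      img <- img * (1 - config$vignette_strength * pmin(dy^2 + dx^2, 1))
    }

    img <- pmin(pmax(img, 0), 1)
    new_spheroid_image(img, id = id,
                       meta = list(fragmentation = frag,
                                   edge_softness = config$edge_softness,
                                   debris_density = config$debris_density,
                                   base_radius = config$base_radius,
                                   rng_seed = config$rng_seed))
  })
}

#' Morphology parameter ranges for the three viability classes
#'
#' Per-class uniform sampling ranges for fragmentation, boundary softness and
#' debris density. Defaults are non-overlapping on the fragmentation axis and
#' ordered unaffected < mildly_affected < affected, so the phenotype the
#' classifier must learn is guaranteed to be present. `separation < 1` pulls
#' the class centres towards each other for harder benchmarks.
#'
#' @param separation scaling of the distance between class centres (1 =
#'   default margins; smaller values shrink the margin)
#' @return named list of class `"class_morph_params"`, one entry per class
#'   with `fragmentation_range`, `edge_softness_range`, `debris_density_range`
#' @export
class_morph_params <- function(separation = 1) {
  stopifnot(separation > 0, separation <= 1)
  base <- list(
    unaffected      = list(fragmentation_range = c(0.00, 0.15),
                           edge_softness_range = c(0.5, 1.5),
                           debris_density_range = c(0.0, 0.1)),
    mildly_affected = list(fragmentation_range = c(0.35, 0.55),
                           edge_softness_range = c(1.5, 3.0),
                           debris_density_range = c(0.2, 0.5)),
    affected        = list(fragmentation_range = c(0.75, 1.00),
                           edge_softness_range = c(3.0, 5.0),
                           debris_density_range = c(0.5, 1.0))
  )
  if (separation < 1) {
    for (cl in names(base)) {
      for (f in names(base[[cl]])) {
        rng <- base[[cl]][[f]]
        mid <- mean(rng); global_mid <- mean(unlist(lapply(base, `[[`, f)))
        new_mid <- global_mid + (mid - global_mid) * separation
        base[[cl]][[f]] <- pmin(pmax(rng - mid + new_mid, 0),
                                if (f == "edge_softness_range") Inf else 1)
      }
    }
  }
  validate_morph_params(base)
  structure(base, class = "class_morph_params")
}

validate_morph_params <- function(p) {
  cls <- spheroid_classes()
  if (!all(cls %in% names(p)))
    stop("morphology parameters must cover all three classes")
  f <- lapply(p[cls], `[[`, "fragmentation_range")
  for (rng in f)
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 1)
      stop("fragmentation ranges must be ordered intervals within [0, 1]")
  if (!(f$unaffected[2] < f$mildly_affected[1] &&
        f$mildly_affected[2] < f$affected[1]))
    stop("class fragmentation ranges must be ordered and non-overlapping ",
         "(unaffected < mildly_affected < affected)")
  invisible(TRUE)
}

#' Render a labelled batch of one viability class
#'
#' Draws per-image fragmentation, boundary softness and debris density
#' uniformly from the class's ranges and renders each image with its own
#' derived seed, so the whole batch is reproducible from `(class, n, seed)`.
#'
#' @param class_name one of [spheroid_classes()]
#' @param morph a [class_morph_params()] set
#' @param n number of images (>= 1)
#' @param seed integer batch seed
#' @param config base [simulation_config()] supplying geometry and nuisance
#'   parameters; its phenotype fields are overridden per image
#' @return list of `"spheroid_image"`, each with `true_class = class_name`
#' @export
render_class <- function(class_name, morph = class_morph_params(), n,
                         seed = 1L, config = simulation_config()) {
  if (!class_name %in% spheroid_classes())
    stop("unknown class name: ", class_name)
  if (n < 1) stop("n must be >= 1")
  validate_morph_params(morph)
  p <- morph[[class_name]]
  draws <- with_seed(seed, data.frame(
    fragmentation = stats::runif(n, p$fragmentation_range[1],
                                 p$fragmentation_range[2]),
    edge_softness = stats::runif(n, p$edge_softness_range[1],
                                 p$edge_softness_range[2]),
    debris_density = stats::runif(n, p$debris_density_range[1],
                                  p$debris_density_range[2]),
    img_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$fragmentation <- draws$fragmentation[i]
    cfg$edge_softness <- draws$edge_softness[i]
    cfg$debris_density <- draws$debris_density[i]
    cfg$rng_seed <- draws$img_seed[i]
    img <- render_spheroid(cfg, id = sprintf("%s_%04d", class_name, i))
    img$true_class <- class_name
    img
  })
}

#' Generate a full labelled synthetic dataset
#'
#' Renders `per_class` images for each of the three viability classes (the
#' reference protocol uses 400 per class, 1,200 in total) and returns them
#' with a manifest.
#'
#' @param per_class images per class
#' @param morph a [class_morph_params()] set
#' @param config base [simulation_config()]
#' @param seed integer seed
#' @return list with `images` (list of `spheroid_image`) and `manifest`
#'   (data frame: `id`, `true_class`, `fragmentation`, `seed`)
#' @export
simulate_dataset <- function(per_class = 400L, morph = class_morph_params(),
                             config = simulation_config(), seed = 1L) {
  cls <- spheroid_classes()
  images <- list()
  for (k in seq_along(cls)) {
    images <- c(images, render_class(cls[k], morph, per_class,
                                     seed = as.integer(seed) + 1000L * k,
                                     config = config))
  }
  manifest <- data.frame(
    id = vapply(images, `[[`, character(1), "id"),
    true_class = vapply(images, `[[`, character(1), "true_class"),
    fragmentation = vapply(images, function(x) x$meta$fragmentation, numeric(1)),
    seed = vapply(images, function(x) x$meta$rng_seed, numeric(1))
  )
  list(images = images, manifest = manifest)
}

#' Write / read a rendered dataset as PNG files plus a CSV manifest
#'
#' Images are written as single-channel PNG (8- or 16-bit); the manifest CSV
#' has columns `image_path`, `id`, `true_class`, `fragmentation`, `seed`.
#'
#' @param dataset result of [simulate_dataset()]
#' @param dir output directory (created if missing)
#' @param bit_depth 8 or 16
#' @return invisibly, the manifest with file paths
#' @export
write_dataset <- function(dataset, dir, bit_depth = 8L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(dataset$images, function(im) {
    path <- file.path(dir, paste0(im$id, ".png"))
    png::writePNG(im$pixels, target = path, dpi = NULL)
    path
  }, character(1))
  manifest <- cbind(image_path = paths, dataset$manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @param manifest_path path to a `manifest.csv` written by [write_dataset()]
#' @export
read_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$image_path[i]
    if (!file.exists(path)) path <- file.path(base, basename(path))
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    new_spheroid_image(px, id = manifest$id[i],
                       true_class = manifest$true_class[i],
                       provenance = "external")
  })
  list(images = images, manifest = manifest)
}
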