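test_that("render_spheroid honours the raster contract and is deterministic", {
  cfg <- smoke_sim_config(seed = 42)
  img <- render_spheroid(cfg)
  expect_s3_class(img, "spheroid_image")
  expect_identical(dim(img$pixels), c(64L, 64L))
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  expect_identical(img$pixels, render_spheroid(cfg)$pixels)
  # a different seed gives a different image
  expect_false(identical(img$pixels,
                         render_spheroid(smoke_sim_config(seed = 43))$pixels))
})

test_that("noise-free unfragmented render is a single sharp component", {
  cfg <- simulation_config(image_height = 96, image_width = 96,
                           base_radius = 24, fragmentation = 0,
                           texture_noise_sd = 0, edge_softness = 0,
                           radius_jitter = 0, rng_seed = 5)
  img <- render_spheroid(cfg)$pixels
  mid <- (min(img) + max(img)) / 2
  lab <- EBImage::bwlabel(EBImage::Image((img > mid) * 1))
  expect_identical(max(as.integer(EBImage::imageData(lab))), 1L)
  # mass area is close to pi * r^2
  expect_lt(abs(sum(img > mid) - pi * 24^2) / (pi * 24^2), 0.15)
})

test_that("invalid geometry and parameters are rejected", {
  expect_error(simulation_config(base_radius = 0), "geometry")
  expect_error(simulation_config(image_height = 64, image_width = 64,
                                 base_radius = 40), "geometry")
  expect_error(simulation_config(fragmentation = 1.2), "fragmentation")
  expect_error(simulation_config(edge_softness = -1), "edge_softness")
})

test_that("edge contrast decreases monotonically along the fragmentation axis", {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  n_seeds <- 20
  means <- vapply(levels, function(f) {
    vals <- vapply(seq_len(n_seeds), function(s) {
      cfg <- smoke_sim_config(seed = 100 + s, fragmentation = f)
      compute_features(render_spheroid(cfg))$edge_contrast
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("edge contrast decreases in edge softness (in expectation)", {
  sigmas <- c(0, 2, 4)
  means <- vapply(sigmas, function(sg) {
    vals <- vapply(1:20, function(s) {
      cfg <- smoke_sim_config(seed = 300 + s, edge_softness = sg)
      compute_features(render_spheroid(cfg))$edge_contrast
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("render_class labels, validates and reproduces batches", {
  imgs <- render_class("mildly_affected", n = 4, seed = 9,
                       config = smoke_sim_config())
  expect_length(imgs, 4)
  expect_true(all(vapply(imgs, `[[`, character(1), "true_class") ==
                    "mildly_affected"))
  imgs2 <- render_class("mildly_affected", n = 4, seed = 9,
                        config = smoke_sim_config())
  expect_identical(lapply(imgs, `[[`, "pixels"), lapply(imgs2, `[[`, "pixels"))
  expect_error(render_class("necrotic", n = 1), "unknown class")
  expect_error(render_class("affected", n = 0), "n must be")
})

test_that("class morphology ranges are ordered and non-overlapping", {
  p <- class_morph_params()
  expect_lt(p$unaffected$fragmentation_range[2],
            p$mildly_affected$fragmentation_range[1])
  expect_lt(p$mildly_affected$fragmentation_range[2],
            p$affected$fragmentation_range[1])
  # a margin-shrunk set that collides must be rejected
  bad <- unclass(class_morph_params())
  bad$unaffected$fragmentation_range <- c(0, 0.5)
  expect_error(validate_morph_params <- spheroidscreen:::validate_morph_params(bad),
               "non-overlapping")
})

test_that("datasets round-trip through PNG + manifest CSV", {
  ds <- smoke_dataset(per_class = 3, seed = 21)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 9)
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_length(back$images, 9)
  expect_identical(back$images[[1]]$true_class, ds$images[[1]]$true_class)
  # 8-bit quantisation: intensities agree to 1/255
  expect_lt(max(abs(back$images[[1]]$pixels - ds$images[[1]]$pixels)), 1 / 255)
})
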