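test_that("segmentation recovers a clean disc to within 2% area", {
  img <- disc_image(128, r = 40)
  m <- segment_spheroid(img)
  expect_false(m$empty)
  expect_equal(m$n_components, 1L)
  expect_lt(abs(sum(m$mask) - pi * 40^2) / (pi * 40^2), 0.02)
})

test_that("blank images yield a flagged empty mask, not an error", {
  m <- segment_spheroid(matrix(0.1, 32, 32))
  expect_true(m$empty)
  expect_equal(m$n_components, 0L)
  f <- compute_features(matrix(0.1, 32, 32), m)
  expect_true(f$empty)
  expect_equal(f$volume_au, 0)
  expect_equal(f$edge_contrast, 0)
})

test_that("sphere-model volume matches the closed form and scales cubically", {
  img <- disc_image(192, r = 50)
  f <- compute_features(img)
  v_expected <- 4 / 3 * pi * 50^3
  expect_lt(abs(f$volume_au - v_expected) / v_expected, 0.05)
  img2 <- disc_image(420, r = 100)
  f2 <- compute_features(img2)
  expect_lt(abs(f2$volume_au / f$volume_au - 8) / 8, 0.05)
})

test_that("edge contrast ranks sharp above blurred boundaries", {
  sharp <- compute_features(disc_image(128, r = 40))$edge_contrast
  soft <- compute_features(disc_image(128, r = 40, blur_sigma = 5))$edge_contrast
  expect_gt(sharp, soft)
  # monotone decrease over a blur sweep
  sweep <- vapply(c(0, 1, 2, 4, 6), function(sg)
    compute_features(disc_image(128, r = 40, blur_sigma = sg))$edge_contrast,
    numeric(1))
  expect_true(all(diff(sweep) < 0))
})

test_that("solidity and component count respond to fragmentation", {
  whole <- render_spheroid(smoke_sim_config(seed = 4, fragmentation = 0,
                                            edge_softness = 0.5))
  frag <- render_spheroid(smoke_sim_config(seed = 4, fragmentation = 1,
                                           edge_softness = 0.5,
                                           debris_density = 0.8))
  fw <- compute_features(whole)
  ff <- compute_features(frag)
  expect_equal(fw$n_components, 1L)
  expect_gte(fw$solidity, ff$solidity)
})

test_that("the edge-contrast baseline separates the default synthetic classes", {
  ds <- smoke_dataset(per_class = 20, seed = 11)
  feats <- morphometry_table(ds$images)
  fit <- fit_morphometry_baseline(feats)
  pred <- predict_morphometry_baseline(fit, feats)
  expect_gte(mean(pred == feats$true_class), 0.8)
  # the class ordering by mean contrast matches the phenotype
  expect_identical(fit$class_order,
                   c("unaffected", "mildly_affected", "affected"))
})
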