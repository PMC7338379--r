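test_that("shape inference reproduces every row of the reference layer table", {
  s <- infer_shapes(model_spec())
  expect_shape <- function(layer, d1, d2 = NA_integer_, d3 = NA_integer_) {
    row <- s[s$layer == layer, ]
    expect_equal(unname(unlist(row[c("dim1", "dim2", "dim3")])),
                 as.integer(c(d1, d2, d3)))
  }
  expect_shape("conv2d_1", 398, 318, 32)
  expect_shape("max_pooling2d_1", 199, 159, 32)
  expect_shape("conv2d_2", 197, 157, 64)
  expect_shape("max_pooling2d_2", 98, 78, 64)
  expect_shape("conv2d_3", 96, 76, 64)
  expect_shape("max_pooling2d_3", 48, 38, 64)
  expect_shape("conv2d_4", 46, 36, 128)
  expect_shape("max_pooling2d_4", 23, 18, 128)
  expect_shape("flatten_1", 52992)
  expect_shape("dense_1", 128)
  expect_shape("dense_2", 3)
})

test_that("parameter counts match the reference table cell by cell", {
  cp <- count_parameters(model_spec())
  per <- cp$per_layer
  get <- function(layer) per$params[per$layer == layer]
  expect_equal(get("conv2d_1"), 320)
  expect_equal(get("conv2d_2"), 18496)
  expect_equal(get("conv2d_3"), 36928)
  expect_equal(get("conv2d_4"), 73856)
  expect_equal(get("dense_1"), 6783104)
  expect_equal(get("dense_2"), 387)
  expect_true(all(per$params[per$kind %in%
    c("activation_relu", "activation_softmax", "maxpool2d", "flatten",
      "dropout")] == 0))
  expect_equal(cp$total, 6913091)
})

test_that("valid-conv boundary arithmetic errors when the input collapses", {
  one <- list(layer_conv2d(4))
  s <- infer_shapes(one, input_shape = c(3, 3, 1))
  expect_equal(unname(unlist(s[1, c("dim1", "dim2", "dim3")])), c(1, 1, 4))
  two <- list(layer_conv2d(4), layer_conv2d(4))
  expect_error(infer_shapes(two, input_shape = c(3, 3, 1)), "too deep")
})

test_that("dense parameter arithmetic and the empty spec behave", {
  d <- list(layer_dense(4))
  expect_equal(count_parameters(d, input_shape = 10)$total, 44)
  expect_identical(count_parameters(list(), input_shape = c(8, 8, 1))$total, 0L)
})

test_that("built models allocate exactly the counted number of parameters", {
  # randomized small specs against the analytic count
  set.seed(99)
  for (i in 1:5) {
    nconv <- sample(1:3, 1)
    filters <- sample(c(2L, 4L, 8L), nconv, replace = TRUE)
    dense <- sample(c(4L, 16L), 1)
    size <- sample(c(24L, 32L, 40L), 1)
    spec <- model_spec(input_shape = c(size, size, 1L),
                       conv_filters = filters, dense_units = dense)
    model <- build_model(spec, seed = i)
    expect_identical(n_parameters(model), as.numeric(count_parameters(spec)$total))
  }
})

test_that("the model summary prints reference-style shapes and total", {
  s <- model_summary(model_spec())
  expect_identical(s$output_shape[s$layer == "conv2d_1"], "(None, 398, 318, 32)")
  expect_identical(s$output_shape[s$layer == "flatten_1"], "(None, 52,992)")
  expect_equal(attr(s, "total"), 6913091)
})
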