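#' Layer descriptions for the spheroid classifier
#'
#' Constructors for the layer vocabulary used by [model_spec()]:
#' valid-padding 2-D convolutions, ReLU/softmax activations, non-overlapping
#' max-pooling, flattening, fully-connected layers and dropout. A layer is a
#' plain list with a `kind` field; [infer_shapes()] and [count_parameters()]
#' consume ordered lists of them.
#'
#' @param filters number of convolution filters (feature maps)
#' @param kernel kernel height/width in pixels (square), default 3
#' @param pool pooling window (square), stride equals the window, floor
#'   division on odd input dimensions
#' @param units number of output units of a dense layer
#' @param rate dropout rate in `[0, 1)`
#' @return a list of class `"spheroid_layer"`
#' @name layers
NULL

new_layer <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "spheroid_layer")
}

#' @rdname layers
#' @export
layer_conv2d <- function(filters, kernel = 3L) {
  stopifnot(filters >= 1, kernel >= 1)
  new_layer("conv2d", filters = as.integer(filters), kernel = as.integer(kernel))
}

#' @rdname layers
#' @export
layer_activation <- function(kind = c("relu", "softmax")) {
  new_layer(paste0("activation_", match.arg(kind)))
}

#' @rdname layers
#' @export
layer_maxpool2d <- function(pool = 2L) {
  stopifnot(pool >= 1)
  new_layer("maxpool2d", pool = as.integer(pool))
}

#' @rdname layers
#' @export
layer_flatten <- function() new_layer("flatten")

#' @rdname layers
#' @export
layer_dense <- function(units) {
  stopifnot(units >= 1)
  new_layer("dense", units = as.integer(units))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.5) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout", rate = rate)
}

#' Specification of the three-class spheroid CNN
#'
#' Builds the ordered layer list of the reference classifier: four
#' conv(3x3, valid) + ReLU + max-pool(2x2) blocks with 32/64/64/128 filters,
#' a flatten, a 128-unit ReLU dense layer with dropout, and a 3-way softmax
#' head. The default 400x320x1 input geometry is the one under which the
#' published layer table (398x318x32 after the first convolution, 52,992
#' flattened features, 6,913,091 trainable parameters) is reproduced exactly;
#' both geometry and widths are configurable for reduced-scale runs.
#'
#' @param input_shape integer vector `(height, width, channels)`
#' @param n_classes number of output classes
#' @param conv_filters filter counts of the convolution blocks, in order
#' @param dense_units width of the penultimate fully-connected layer
#' @param dropout_rate dropout after the dense ReLU layer
#' @return an object of class `"spheroid_model_spec"`: a list with `layers`
#'   (ordered `spheroid_layer`s), `input_shape` and `n_classes`
#' @examples
#' spec <- model_spec()
#' count_parameters(spec)$total  # 6913091
#' @export
model_spec <- function(input_shape = c(400L, 320L, 1L), n_classes = 3L,
                       conv_filters = c(32L, 64L, 64L, 128L),
                       dense_units = 128L, dropout_rate = 0.5) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("input_shape must be three positive integers (height, width, channels)")
  if (length(conv_filters) < 1L) stop("at least one convolution block required")
  layers <- list()
  for (f in conv_filters) {
    layers <- c(layers, list(layer_conv2d(f), layer_activation("relu"),
                             layer_maxpool2d()))
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(dense_units), layer_activation("relu"),
    layer_dropout(dropout_rate),
    layer_dense(n_classes), layer_activation("softmax")
  ))
  structure(
    list(layers = layers, input_shape = input_shape,
         n_classes = as.integer(n_classes),
         conv_filters = as.integer(conv_filters),
         dense_units = as.integer(dense_units), dropout_rate = dropout_rate),
    class = "spheroid_model_spec"
  )
}

layer_names <- function(layers) {
  counts <- integer(0)
  vapply(layers, function(l) {
    base <- switch(l$kind,
      conv2d = "conv2d", maxpool2d = "max_pooling2d", flatten = "flatten",
      dense = "dense", dropout = "dropout",
      activation_relu = "activation", activation_softmax = "activation",
      stop("unknown layer kind: ", l$kind))
    counts[base] <<- if (is.na(counts[base])) 1L else counts[base] + 1L
    sprintf("%s_%d", base, counts[[base]])
  }, character(1))
}

#' Infer per-layer output shapes
#'
#' Propagates a `(height, width, channels)` input through an ordered layer
#' list using valid-convolution arithmetic (`out = in - kernel + 1`) and
#' floor-division pooling (`out = floor(in / pool)`). Dense and flatten
#' layers produce 1-D feature shapes.
#'
#' @param spec a `"spheroid_model_spec"` (or a bare list of layers, in which
#'   case `input_shape` must be given)
#' @param input_shape optional `(h, w, c)` override
#' @return a data frame with columns `layer`, `kind`, `dim1`, `dim2`, `dim3`;
#'   spatial layers fill all three dims, flat layers put the feature count in
#'   `dim1` and `NA` elsewhere
#' @export
infer_shapes <- function(spec, input_shape = NULL) {
  layers <- if (inherits(spec, "spheroid_model_spec")) spec$layers else spec
  if (is.null(input_shape)) {
    if (!inherits(spec, "spheroid_model_spec"))
      stop("input_shape required when passing a bare layer list")
    input_shape <- spec$input_shape
  }
  shape <- as.integer(input_shape)  # c(h, w, c) or c(features)
  nms <- layer_names(layers)
  out <- data.frame(layer = nms,
                    kind = vapply(layers, `[[`, character(1), "kind"),
                    dim1 = NA_integer_, dim2 = NA_integer_, dim3 = NA_integer_)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "conv2d") {
      if (length(shape) != 3L) stop("conv2d applied to non-spatial input")
      hw <- shape[1:2] - l$kernel + 1L
      if (any(hw < 1L))
        stop("network too deep for input: conv2d input ", shape[1], "x",
             shape[2], " is smaller than the ", l$kernel, "x", l$kernel,
             " kernel")
      shape <- c(hw, l$filters)
    } else if (l$kind == "maxpool2d") {
      if (length(shape) != 3L) stop("maxpool2d applied to non-spatial input")
      hw <- shape[1:2] %/% l$pool
      if (any(hw < 1L)) stop("network too deep for input: pooling collapsed a dimension")
      shape <- c(hw, shape[3])
    } else if (l$kind == "flatten") {
      shape <- as.integer(prod(shape))
    } else if (l$kind == "dense") {
      if (length(shape) != 1L) stop("dense layer requires flattened input")
      shape <- l$units
    }
    # activations and dropout leave the shape untouched
    out[i, c("dim1", "dim2", "dim3")] <-
      as.integer(c(shape, rep(NA_integer_, 3 - length(shape))))
  }
  out
}

#' Count trainable parameters
#'
#' Convolution layers contribute `kh * kw * c_in * c_out + c_out` parameters,
#' dense layers `n_in * n_out + n_out`; activations, pooling, flatten and
#' dropout contribute none.
#'
#' @inheritParams infer_shapes
#' @return a list with `per_layer` (data frame: `layer`, `kind`, `params`)
#'   and `total`
#' @export
count_parameters <- function(spec, input_shape = NULL) {
  layers <- if (inherits(spec, "spheroid_model_spec")) spec$layers else spec
  if (is.null(input_shape) && inherits(spec, "spheroid_model_spec"))
    input_shape <- spec$input_shape
  if (length(layers) == 0L)
    return(list(per_layer = data.frame(layer = character(0), kind = character(0),
                                       params = integer(0)), total = 0L))
  shapes <- infer_shapes(layers, input_shape)
  params <- integer(nrow(shapes))
  shape_in <- as.integer(input_shape)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "conv2d") {
      params[i] <- l$kernel * l$kernel * shape_in[3] * l$filters + l$filters
    } else if (l$kind == "dense") {
      params[i] <- shape_in[1] * l$units + l$units
    }
    shape_in <- as.integer(stats::na.omit(unlist(shapes[i, c("dim1", "dim2", "dim3")])))
  }
  list(per_layer = data.frame(layer = shapes$layer, kind = shapes$kind,
                              params = params),
       total = sum(params))
}

#' Keras-style model summary table
#'
#' @inheritParams infer_shapes
#' @return data frame with `layer`, `output_shape` (printed as
#'   `"(None, h, w, c)"`), `params`, plus a `total` attribute
#' @export
model_summary <- function(spec) {
  shapes <- infer_shapes(spec)
  counts <- count_parameters(spec)
  fmt <- function(i) {
    d <- unlist(shapes[i, c("dim1", "dim2", "dim3")])
    d <- d[!is.na(d)]
    paste0("(None, ", paste(format(d, big.mark = ",", trim = TRUE),
                            collapse = ", "), ")")
  }
  out <- data.frame(layer = shapes$layer,
                    output_shape = vapply(seq_len(nrow(shapes)), fmt, character(1)),
                    params = counts$per_layer$params)
  attr(out, "total") <- counts$total
  out
}

#' @export
print.spheroid_model_spec <- function(x, ...) {
  s <- model_summary(x)
  cat("Spheroid classifier specification (input ",
      paste(x$input_shape, collapse = "x"), ")\n", sep = "")
  print(s, row.names = FALSE)
  cat("Total trainable parameters:",
      format(attr(s, "total"), big.mark = ","), "\n")
  invisible(x)
}
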