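#' @useDynLib spheroidscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

spec_arch <- function(spec) {
  stopifnot(inherits(spec, "spheroid_model_spec"))
  list(input = as.integer(spec$input_shape),
       conv_filters = as.integer(spec$conv_filters),
       kernel = 3L, pool = 2L,
       dense_units = as.integer(spec$dense_units),
       n_classes = as.integer(spec$n_classes))
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build a trainable CNN instance from a specification
#'
#' Allocates Glorot-uniform weights for every convolution and dense layer of
#' `spec` and returns a handle that [train_model()] and [predict_proba()]
#' operate on. The reported trainable-parameter total always equals
#' [count_parameters()] on the same spec.
#'
#' @param spec a [model_spec()]
#' @param dropout_rate optional override of the spec's dropout rate
#' @param seed integer seed for weight initialization
#' @return an object of class `"spheroid_cnn"`
#' @export
build_model <- function(spec, dropout_rate = NULL, seed = 1L) {
  arch <- spec_arch(spec)
  shapes <- infer_shapes(spec)
  if (is.null(dropout_rate)) dropout_rate <- spec$dropout_rate
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  with_seed(seed, {
    weights <- list()
    cin <- arch$input[3]
    for (f in arch$conv_filters) {
      fan_in <- 9L * cin
      weights <- c(weights, list(glorot(f, 9L * cin, fan_in, f),
                                 numeric(f)))
      cin <- f
    }
    flat_row <- which(shapes$kind == "flatten")
    flat <- shapes$dim1[flat_row]
    weights <- c(weights,
                 list(glorot(arch$dense_units, flat, flat, arch$dense_units),
                      numeric(arch$dense_units),
                      glorot(arch$n_classes, arch$dense_units,
                             arch$dense_units, arch$n_classes),
                      numeric(arch$n_classes)))
  })
  zeros <- lapply(weights, function(w) w * 0)
  structure(list(spec = spec, arch = arch, weights = weights,
                 dropout_rate = dropout_rate,
                 adam = list(m = zeros, v = zeros, t = 0L),
                 history = data.frame(epoch = integer(0), acc = numeric(0),
                                      val_acc = numeric(0))),
            class = "spheroid_cnn")
}

#' Number of trainable parameters actually allocated in a model
#'
#' @param model a `"spheroid_cnn"`
#' @return integer total over all weight arrays
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "spheroid_cnn"))
  sum(vapply(model$weights, length, numeric(1)))
}

# Stack a list of h x w matrices (or a single matrix) into an h x w x n array.
stack_images <- function(images) {
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "spheroid_image")) images <- list(images)
  pix <- lapply(images, function(im) {
    if (inherits(im, "spheroid_image")) im$pixels else im
  })
  d <- dim(pix[[1]])
  for (p in pix) {
    if (!identical(dim(p), d))
      stop("all images must share one raster shape (found ",
           paste(dim(p), collapse = "x"), " vs ", paste(d, collapse = "x"), ")")
  }
  array(unlist(pix, use.names = FALSE), dim = c(d, length(pix)))
}

#' Class probabilities for a batch of images
#'
#' @param model a trained or untrained `"spheroid_cnn"`
#' @param images list of numeric matrices (or `spheroid_image`s) matching the
#'   model's input geometry
#' @return numeric matrix, one row per image, columns summing to 1
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "spheroid_cnn"))
  X <- stack_images(images)
  p <- cnn_predict_proba_cpp(model$weights, model$arch, X)
  colnames(p) <- spheroid_classes()
  p
}

#' Train a model in place for a number of epochs
#'
#' Runs shuffled mini-batch Adam on categorical cross-entropy. Augmentation,
#' when supplied, is re-drawn every epoch and applied to the training images
#' only; validation accuracy is computed on the clean validation rasters.
#'
#' @param model a `"spheroid_cnn"`
#' @param images,labels training images (list of matrices) and factor/character
#'   labels over [spheroid_classes()]
#' @param val_images,val_labels optional held-out fold for per-epoch validation
#'   accuracy
#' @param epochs number of passes over the training data (must be >= 1)
#' @param batch_size mini-batch size
#' @param lr Adam learning rate
#' @param augmentation optional [augmentation_config()] applied per epoch
#' @param seed integer; drives shuffling, dropout and augmentation draws
#' @param verbose print per-epoch progress
#' @return the updated model, with `$history` holding per-epoch accuracy
#' @export
train_model <- function(model, images, labels, val_images = NULL,
                        val_labels = NULL, epochs = 50L, batch_size = 32L,
                        lr = 1e-3, augmentation = NULL, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "spheroid_cnn"))
  if (epochs < 1L) stop("epochs must be >= 1 (an untrained model has no curves)")
  if (length(images) == 0L) stop("empty training set")
  y <- encode_labels(labels)
  if (length(y) != length(images)) stop("labels do not match image count")
  Xval <- if (!is.null(val_images)) stack_images(val_images) else NULL
  yval <- if (!is.null(val_labels)) encode_labels(val_labels) else NULL
  for (e in seq_len(epochs)) {
    ep_seed <- (as.integer(seed) + 7919L * e) %% .Machine$integer.max
    xs <- if (is.null(augmentation)) images else
      augment_batch(images, augmentation, seed = ep_seed)
    X <- stack_images(xs)
    res <- cnn_train_epoch_cpp(model$weights, model$adam$m, model$adam$v,
                               model$adam$t, model$arch, X, y,
                               lr, 0.9, 0.999, 1e-8,
                               model$dropout_rate, as.integer(batch_size),
                               ep_seed)
    model$weights <- res$weights
    model$adam <- list(m = res$m, v = res$v, t = res$t)
    val_acc <- NA_real_
    if (!is.null(Xval)) {
      pv <- cnn_predict_proba_cpp(model$weights, model$arch, Xval)
      val_acc <- mean(max.col(pv) - 1L == yval)
    }
    model$history <- rbind(model$history,
                           data.frame(epoch = nrow(model$history) + 1L,
                                      acc = res$train_acc, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  acc %.3f  val_acc %s",
                      e, epochs, res$loss, res$train_acc,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  model
}

#' The three viability classes, in canonical order
#' @return character vector `c("unaffected", "mildly_affected", "affected")`
#' @export
spheroid_classes <- function() c("unaffected", "mildly_affected", "affected")

encode_labels <- function(labels) {
  labels <- as.character(labels)
  cls <- spheroid_classes()
  bad <- setdiff(unique(labels), cls)
  if (length(bad) > 0)
    stop("unlabeled or unknown classes in label vector: ",
         paste(bad, collapse = ", "))
  match(labels, cls) - 1L
}

#' @export
print.spheroid_cnn <- function(x, ...) {
  cat("Spheroid CNN (", format(n_parameters(x), big.mark = ","),
      " parameters, dropout ", x$dropout_rate, ")\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("trained %d epochs; acc %.3f, val_acc %s\n",
                nrow(x$history), last$acc,
                ifelse(is.na(last$val_acc), "-", sprintf("%.3f", last$val_acc))))
  } else cat("untrained\n")
  invisible(x)
}
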