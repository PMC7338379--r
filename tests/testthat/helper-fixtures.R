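# Shared fixtures. Everything is generated in code; the small geometries keep
# the default run fast while exercising the same code paths as the full
# 400x320 protocol.

smoke_sim_config <- function(seed = 1L, ...) {
  simulation_config(image_height = 64L, image_width = 64L, base_radius = 16,
                    rng_seed = seed, ...)
}

smoke_model_spec <- function() model_spec(input_shape = c(64L, 64L, 1L))

# A synthetic disc image: bright disc of radius r on a dark background.
disc_image <- function(size = 128L, r = 40, fg = 0.8, bg = 0.05,
                       blur_sigma = 0) {
  cy <- (size + 1) / 2
  dy <- matrix(seq_len(size) - cy, size, size)
  dx <- t(dy)
  img <- ifelse(sqrt(dy^2 + dx^2) <= r, fg, bg)
  if (blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  img
}

# Memoised smoke dataset shared across test files (rendered once per run).
.fixture_env <- new.env(parent = emptyenv())

smoke_dataset <- function(per_class = 20L, seed = 11L) {
  key <- sprintf("ds_%d_%d", per_class, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(per_class = per_class,
                                            config = smoke_sim_config(),
                                            seed = seed)
  }
  .fixture_env[[key]]
}

# Independent brute-force metric oracle: per-class precision/recall/F1 by
# explicit TP/FP/FN counting from a label pair list.
oracle_metrics <- function(cm) {
  k <- nrow(cm)
  out <- data.frame(precision = numeric(k), recall = numeric(k),
                    f1 = numeric(k))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    out$precision[i] <- p
    out$recall[i] <- r
    out$f1[i] <- if (p + r > 0) 2 * (p * r) / (p + r) else 0
  }
  out
}
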