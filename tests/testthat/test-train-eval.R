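fake_manifest <- function(per_class = 400L) {
  data.frame(id = sprintf("img_%04d", seq_len(3 * per_class)),
             true_class = rep(spheroid_classes(), each = per_class))
}

test_that("the 80/20 split and five folds reproduce the protocol arithmetic", {
  man <- fake_manifest(400)
  plan <- make_splits(man, seed = 1)
  expect_length(plan$test_idx, 240)
  pool <- setdiff(seq_len(1200), plan$test_idx)
  expect_length(pool, 960)
  for (f in plan$folds) {
    expect_length(f$val_idx, 192)
    expect_length(f$train_idx, 768)
    expect_length(intersect(f$val_idx, plan$test_idx), 0)
    expect_setequal(union(f$train_idx, f$val_idx), pool)
  }
  # validation folds partition the pool
  vals <- lapply(plan$folds, `[[`, "val_idx")
  expect_setequal(unlist(vals), pool)
  expect_equal(sum(lengths(vals)), length(pool))
})

test_that("splits are deterministic, stratified, and validated", {
  man <- fake_manifest(25)
  p1 <- make_splits(man, seed = 9)
  p2 <- make_splits(man, seed = 9)
  expect_identical(p1, p2)
  p3 <- make_splits(man, seed = 10)
  expect_false(identical(p1$test_idx, p3$test_idx))
  # stratification: each class contributes 20% to the test set
  tc <- table(man$true_class[p1$test_idx])
  expect_true(all(tc == 5))
  expect_error(make_splits(man, n_folds = 1), "n_folds")
  expect_error(make_splits(fake_manifest(3), n_folds = 5), "too few")
  man_un <- man; man_un$true_class[1] <- "unlabeled"
  expect_error(make_splits(man_un), "unlabeled")
})

test_that("fold partition correctness holds over random manifest sizes", {
  set.seed(42)
  for (rep in 1:10) {
    per <- sample(10:60, 1)
    k <- sample(2:6, 1)
    man <- fake_manifest(per)
    plan <- make_splits(man, n_folds = k, seed = rep)
    pool <- setdiff(seq_len(nrow(man)), plan$test_idx)
    vals <- lapply(plan$folds, `[[`, "val_idx")
    expect_setequal(unlist(vals), pool)
    expect_equal(anyDuplicated(unlist(vals)), 0)
    expect_lte(diff(range(lengths(vals))), 1)
  }
})

test_that("metrics match a brute-force oracle on random confusion matrices", {
  set.seed(7)
  for (rep in 1:200) {
    cm <- matrix(rpois(9, lambda = sample(1:20, 1)), 3, 3,
                 dimnames = list(spheroid_classes(), spheroid_classes()))
    got <- metrics_from_confusion(cm)
    want <- oracle_metrics(cm)
    expect_equal(got$per_class$precision, want$precision)
    expect_equal(got$per_class$recall, want$recall)
    expect_equal(got$per_class$f1, want$f1)
    expect_equal(got$accuracy, sum(diag(cm)) / max(sum(cm), 1))
    # F1 lies between min and max of precision/recall
    ok <- want$f1 <= pmax(want$precision, want$recall) + 1e-12 &
          want$f1 >= pmin(want$precision, want$recall) - 1e-12
    expect_true(all(ok))
  }
})

test_that("hand-computed confusion example gives the expected class metrics", {
  cm <- matrix(c(8, 1, 1,
                 0, 9, 1,
                 2, 0, 8), 3, 3, byrow = TRUE,
               dimnames = list(spheroid_classes(), spheroid_classes()))
  m <- metrics_from_confusion(cm)
  expect_equal(m$per_class$precision[1], 0.8)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$f1[1], 0.8)
  # equal precision and recall give the same F1 (harmonic mean identity)
  expect_equal(2 * (0.9 * 0.9) / (0.9 + 0.9), 0.9)
})

test_that("evaluate reports perfect metrics for perfect predictions", {
  ds <- smoke_dataset(per_class = 20, seed = 11)
  # an untrained model will not be perfect; check the identity on a mock by
  # feeding the confusion path directly
  labs <- ds$manifest$true_class[1:12]
  cm <- confusion_matrix(labs, labs)
  m <- metrics_from_confusion(cm)
  expect_true(all(m$per_class$precision[m$per_class$support > 0] == 1))
  expect_true(all(m$per_class$recall[m$per_class$support > 0] == 1))
  expect_equal(m$accuracy, 1)
  expect_error(confusion_matrix(c("unaffected", "unlabeled"),
                                c("unaffected", "affected")), "unlabeled")
})

test_that("cross-validated training learns the smoke problem end to end", {
  ds <- smoke_dataset(per_class = 20, seed = 11)
  plan <- make_splits(ds$manifest, seed = 2)
  cv <- train_cv(ds$images, ds$manifest$true_class, plan, smoke_model_spec(),
                 augmentation = augmentation_config(), epochs = 6,
                 batch_size = 8, seed = 2)
  expect_equal(nrow(cv$curves), 6)
  expect_identical(names(cv$curves), c("epoch", "acc_avg", "val_acc_avg"))
  expect_equal(length(cv$fold_final_val_acc), 5)
  expect_equal(cv$best_fold, which.max(cv$fold_final_val_acc))
  # learning happened: averaged accuracy improves over the run
  expect_gt(cv$curves$acc_avg[6], cv$curves$acc_avg[1])
  rep <- evaluate(cv$best_model, ds$images[plan$test_idx],
                  ds$manifest$true_class[plan$test_idx])
  expect_s3_class(rep, "metrics_report")
  expect_equal(sum(rep$confusion_matrix), length(plan$test_idx))
  expect_equal(unname(rowSums(rep$confusion_matrix)),
               as.vector(table(ds$manifest$true_class[plan$test_idx])[
                 spheroid_classes()]))
  expect_error(train_cv(ds$images, ds$manifest$true_class, plan,
                        smoke_model_spec(), epochs = 0), "epochs")
})
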