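test_that("confusion counts follow the acceptable-positive convention", {
  cm <- confusion_matrix(c(1, 1, 1, 1, 0, 0, 0, 0),
                         c(1, 1, 1, 0, 1, 1, 0, 0))
  expect_identical(cm[c("TP", "FN", "FP", "TN")],
                   list(TP = 3L, FN = 1L, FP = 2L, TN = 2L))
  same <- confusion_matrix(rep("acceptable", 4), rep("acceptable", 4))
  expect_identical(same$FP + same$FN, 0L)
  allwrong <- confusion_matrix(rep("acceptable", 5), rep("unacceptable", 5))
  expect_identical(allwrong$TP, 0L)
  expect_identical(allwrong$FN, 5L)
  expect_error(confusion_matrix(1:3 > 1, c(TRUE, FALSE)), "length")
  expect_error(confusion_matrix(c("good", "bad"), c("good", "bad")),
               "binary")
})

test_that("the five scores match their closed forms", {
  perfect <- compute_metrics(confusion_matrix(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unname(perfect[c("Se", "Sp", "F1", "Acc", "mAcc")]),
               rep(100, 5))
  m <- compute_metrics(confusion_matrix(c(1, 1, 1, 1, 0, 0, 0, 0),
                                        c(1, 1, 1, 0, 1, 1, 0, 0)))
  expect_equal(unname(m["Se"]), 75)
  expect_equal(unname(m["Sp"]), 50)
  expect_equal(unname(m["Acc"]), 62.5)
  expect_equal(unname(m["F1"]), 100 * 3 / (3 + 0.5 * 3))
  expect_equal(unname(m["mAcc"]), 62.5)
  # identities on random confusion matrices
  set.seed(44)
  for (i in 1:30) {
    y <- sample(c(0, 1), 60, replace = TRUE)
    p <- sample(c(0, 1), 60, replace = TRUE)
    if (length(unique(y)) < 2) next
    cm <- confusion_matrix(y, p)
    mm <- compute_metrics(cm)
    expect_equal(unname(mm["mAcc"]), unname((mm["Se"] + mm["Sp"]) / 2))
    expect_equal(unname(mm["Acc"]),
                 100 * (cm$TP + cm$TN) / sum(unlist(cm)))
    if (cm$TP + cm$FP > 0 && cm$TP > 0) {
      prec <- cm$TP / (cm$TP + cm$FP)
      rec <- unname(mm["Se"]) / 100
      expect_equal(unname(mm["F1"]), 100 * 2 * prec * rec / (prec + rec),
                   tolerance = 1e-12)
    }
    # swapping the positive class swaps Se and Sp, fixes Acc and mAcc
    sw <- compute_metrics(confusion_matrix(1 - y, 1 - p))
    expect_equal(unname(sw["Se"]), unname(mm["Sp"]))
    expect_equal(unname(sw["Sp"]), unname(mm["Se"]))
    expect_equal(unname(sw["Acc"]), unname(mm["Acc"]))
    expect_equal(unname(sw["mAcc"]), unname(mm["mAcc"]))
  }
})

test_that("k-fold splits partition deterministically with stratification", {
  f <- kfold_split(998, 10, seed = 3)
  sizes <- sort(lengths(f))
  expect_identical(sizes, c(99L, 99L, rep(100L, 8L)))
  expect_identical(sort(unlist(f)), 1:998)
  expect_identical(f, kfold_split(998, 10, seed = 3))
  expect_false(identical(f, kfold_split(998, 10, seed = 4)))
  y <- rep(c("acceptable", "unacceptable"), c(700, 298))
  fs <- kfold_split(998, 10, labels = y, seed = 5)
  pos_per_fold <- vapply(fs, function(i) sum(y[i] == "acceptable"),
                         integer(1))
  expect_lte(diff(range(pos_per_fold)), 1L)
  expect_identical(sort(unlist(fs)), 1:998)
  expect_error(kfold_split(5, 10), "k <= n")
})

test_that("classifier backends separate distinct image families", {
  set <- toy_image_set(30)
  train_idx <- 1:40
  test_idx <- 41:60
  for (backend in c("baseline_cnn", "linear_pixels")) {
    model <- train_classifier(set$images[train_idx],
                              set$labels[train_idx], backend, seed = 2)
    pred <- predict(model, set$images[test_idx])
    acc <- mean(pred == set$labels[test_idx])
    expect_gte(acc, 0.9)
    # determinism: same data + seed reproduce predictions exactly
    model2 <- train_classifier(set$images[train_idx],
                               set$labels[train_idx], backend, seed = 2)
    expect_identical(predict(model2, set$images[test_idx]), pred)
    probs <- predict(model, set$images[test_idx], type = "prob")
    expect_true(all(probs >= 0 & probs <= 1))
  }
  expect_error(train_classifier(set$images[1:4], rep("acceptable", 4)),
               "both classes")
  expect_error(train_classifier(set$images, set$labels,
                                backend = "googlenet_transfer"),
               "pretrained")
  expect_error(train_classifier(set$images[1:3], set$labels[1:2]), "length")
})

test_that("cross-validation summarizes folds without leakage", {
  set <- toy_image_set(20, side = 64L)
  cv <- cross_validate(set$images, set$labels, k = 5,
                       backend = "linear_pixels", seed = 6)
  expect_identical(nrow(cv$per_fold), 5L)
  expect_true(all(as.matrix(cv$per_fold) >= 0 & as.matrix(cv$per_fold) <= 100))
  for (m in names(cv$mean)) {
    expect_gte(cv$mean[[m]], min(cv$per_fold[[m]]))
    expect_lte(cv$mean[[m]], max(cv$per_fold[[m]]))
  }
  expect_gte(cv$mean[["Acc"]], 95)  # separable by construction
  cv2 <- cross_validate(set$images, set$labels, k = 5,
                        backend = "linear_pixels", seed = 6)
  expect_identical(cv$per_fold, cv2$per_fold)
  # no test-fold leakage: corrupting the held-out fold cannot change the
  # model fitted on the remaining folds
  spoiled <- set$images
  for (i in cv$folds[[1L]])
    spoiled[[i]] <- structure(array(0L, dim(unclass(spoiled[[i]]))),
                              class = class(spoiled[[i]]))
  keep <- setdiff(seq_along(set$images), cv$folds[[1L]])
  m1 <- train_classifier(set$images[keep], set$labels[keep],
                         "linear_pixels", seed = 9)
  m2 <- train_classifier(spoiled[keep], set$labels[keep],
                         "linear_pixels", seed = 9)
  expect_identical(m1$beta, m2$beta)
})
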