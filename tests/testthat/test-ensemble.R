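test_that("constant training targets give a constant predictor", {
  set.seed(2)
  ids <- sprintf("l%03d", 1:60)
  blk <- feature_block(matrix(rnorm(60 * 4), 60), ids, name = "x")
  rec <- tibble::tibble(ligand_id = ids, dg = rep(-10, 60))
  ens <- train_ensemble(blk, rec, hyper = fast_hyper(1L), k_folds = 5)
  pred <- predict(ens, blk)
  expect_true(all(abs(pred$mean_dg - (-10)) < 0.1))
})

test_that("a noiseless linear map is recovered below 0.2 kcal/mol held out", {
  set.seed(3)
  n <- 500L
  ids <- sprintf("l%04d", 1:n)
  x <- matrix(rnorm(n * 6), n)
  w <- c(1.5, -2, 0.5, 1, -1, 0.8)
  dg <- drop(x %*% w) - 11
  blk <- feature_block(x, ids, name = "x")
  tr <- ids[1:400]
  rec <- tibble::tibble(ligand_id = tr, dg = dg[1:400])
  ens <- train_ensemble(blk, rec,
                        hyper = train_hyper(hidden_layer_widths = c(64, 32),
                                            epochs = 1500, seed = 4),
                        k_folds = 5)
  pred <- predict(ens, blk, ligand_ids = ids[401:500])
  expect_lt(sqrt(mean((pred$mean_dg - dg[401:500])^2)), 0.2)
})

test_that("training is bit-reproducible under a fixed seed", {
  tt <- test_trained()
  ens2 <- train_ensemble(tt$landscape$features, tt$records,
                         hyper = fast_hyper(3L), k_folds = 5)
  p1 <- predict(tt$ensemble, tt$landscape$features, tt$held_ids)
  p2 <- predict(ens2, tt$landscape$features, tt$held_ids)
  expect_identical(attr(p1, "member_values"), attr(p2, "member_values"))
  expect_identical(tt$ensemble$cv_rmse, ens2$cv_rmse)
})

test_that("fold assignments partition the training set every repeat", {
  tt <- test_trained()
  ens <- train_ensemble(tt$landscape$features, tt$records,
                        hyper = fast_hyper(5L), k_folds = 5, n_repeats = 2)
  expect_length(ens$members, 10L)
  for (folds in ens$fold_assignments) {
    expect_setequal(names(folds), tt$records$ligand_id)
    expect_setequal(unique(folds), 1:5)
    expect_length(folds, nrow(tt$records))  # each ligand exactly once
  }
  # different repeats use different splits
  expect_false(identical(ens$fold_assignments[[1]],
                         ens$fold_assignments[[2]]))
})

test_that("ensemble mean is the exact member mean and spread is the stderr", {
  stub <- stub_linear_ensemble(c(-10, -12))
  blk <- feature_block(matrix(rnorm(6), 3, 2,
                              dimnames = list(NULL, c("f1", "f2"))),
                       c("a", "b", "c"), name = "stub")
  pred <- predict(stub, blk)
  expect_equal(pred$mean_dg, rep(-11, 3))
  expect_equal(pred$stderr_dg, rep(1, 3))  # sd(c(-10,-12))/sqrt(2) = 1
  mv <- attr(pred, "member_values")
  expect_equal(pred$mean_dg, unname(rowMeans(mv)))
  single <- stub_linear_ensemble(-10)
  expect_equal(predict(single, blk)$stderr_dg, rep(0, 3))
})

test_that("prediction spread shrinks as repeats are added", {
  set.seed(6)
  ids <- sprintf("l%03d", 1:80)
  x <- matrix(rnorm(80 * 4), 80)
  blk <- feature_block(x, ids, name = "x")
  rec <- tibble::tibble(ligand_id = ids[1:60],
                        dg = drop(x[1:60, ] %*% c(1, -1, 2, 0.5)) - 10 +
                          rnorm(60, sd = 0.5))
  probe <- ids[61:80]
  spread <- function(n_rep) {
    preds <- vapply(1:6, function(s) {
      ens <- train_ensemble(blk, rec, hyper = fast_hyper(100L + s),
                            k_folds = 5, n_repeats = n_rep)
      predict(ens, blk, probe)$mean_dg
    }, numeric(length(probe)))
    mean(apply(preds, 1, var))
  }
  expect_lt(spread(3L), spread(1L))
})

test_that("the target affine transform round-trips to kcal/mol", {
  tt <- test_trained()
  ens <- train_ensemble(tt$landscape$features, tt$records,
                        hyper = train_hyper(hidden_layer_widths = c(16, 8),
                                            epochs = 800, seed = 9,
                                            target_scale = 2,
                                            target_bias = -12),
                        k_folds = 5)
  pred <- predict(ens, tt$landscape$features, tt$held_ids)
  tru <- tt$landscape$truth$dg_true[match(tt$held_ids,
                                          tt$landscape$truth$ligand_id)]
  expect_lt(sqrt(mean((pred$mean_dg - tru)^2)), 1.5)
  expect_lt(abs(mean(pred$mean_dg) - mean(tru)), 1)
})

test_that("members abort cleanly on divergence and missing features error", {
  tt <- test_trained()
  expect_error(
    train_ensemble(tt$landscape$features,
                   tibble::tibble(ligand_id = "nope", dg = -10),
                   hyper = fast_hyper()),
    "missing")
  blk2 <- feature_block(matrix(0, 2, 1, dimnames = list(NULL, "zz")),
                        c("a", "b"))
  expect_error(predict(tt$ensemble, blk2, c("a", "b")), "lacks")
})

test_that("integrated gradients match the closed form on a linear model", {
  set.seed(8)
  n <- 200L
  ids <- sprintf("l%03d", 1:n)
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x1"))
  dg <- drop(3 * x) - 10
  blk <- feature_block(x, ids, name = "lin")
  rec <- tibble::tibble(ligand_id = ids, dg = dg)
  ens <- train_ensemble(blk, rec,
                        hyper = train_hyper(hidden_layer_widths = integer(0),
                                            epochs = 500, seed = 2),
                        k_folds = 5)
  probe <- ids[1:20]
  ig <- integrated_gradients(ens, blk, probe, m_steps = 256)
  # closed form: attribution = weight * (input - baseline), baseline 0,
  # averaged over the (linear) members in standardized space
  w_eff <- mean(vapply(ens$members,
                       function(m) m$model$W[[1]][1, 1], numeric(1)))
  x_std <- (x[1:20, 1] - ens$center) / ens$scale
  closed <- x_std * w_eff * ens$target_scale
  expect_equal(unname(ig[, 1]), unname(closed), tolerance = 1e-6)
  # and the fitted slope itself recovers the generating map
  expect_equal(w_eff * ens$target_scale / ens$scale, 3, tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("constant features get zero importance and only they are dropped", {
  set.seed(9)
  n <- 150L
  ids <- sprintf("l%03d", 1:n)
  x <- cbind(signal = rnorm(n), flat = rep(2, n))
  dg <- 2 * x[, "signal"] - 10
  blk <- feature_block(x, ids, name = "mix")
  rec <- tibble::tibble(ligand_id = ids, dg = dg)
  ens <- train_ensemble(blk, rec, hyper = fast_hyper(4L), k_folds = 5)
  kept <- importance_filter(ens, blk, threshold = 0.02)
  imp <- attr(kept, "importance")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  expect_equal(kept, "signal", ignore_attr = TRUE)
  # threshold zero keeps everything
  all_kept <- importance_filter(ens, blk, threshold = 0)
  expect_setequal(as.character(all_kept), c("signal", "flat"))
  expect_error(importance_filter(ens, blk, threshold = 10), "lower")
})
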