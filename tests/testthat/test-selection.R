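test_that("greedy picks the most negative predictions with lexicographic ties", {
  preds <- tibble::tibble(ligand_id = c("A", "B", "C"),
                          mean_dg = c(-10, -12, -8),
                          uncertainty = c(1, 1, 1))
  expect_equal(select_greedy(preds, batch_size = 2)$ligand_id, c("B", "A"))
  tie <- tibble::tibble(ligand_id = c("E", "D"), mean_dg = c(-10, -10),
                        uncertainty = 0)
  expect_equal(select_greedy(tie, batch_size = 2)$ligand_id, c("D", "E"))
  expect_warning(out <- select_greedy(preds, excluded = c("A", "B", "C"),
                                      batch_size = 2), "exhausted")
  expect_equal(nrow(out), 0L)
})

test_that("uncertainty selection ranks by prediction spread", {
  preds <- tibble::tibble(ligand_id = c("A", "B", "C"),
                          mean_dg = c(-10, -12, -8),
                          uncertainty = c(0.5, 0.1, 2))
  expect_equal(select_uncertain(preds, batch_size = 2)$ligand_id,
               c("C", "A"))
  tie <- tibble::tibble(ligand_id = c("E", "D"), mean_dg = 0,
                        uncertainty = c(1, 1))
  expect_equal(select_uncertain(tie, batch_size = 1)$ligand_id, "D")
})

test_that("mixed selection reduces to greedy and uncertain at its limits", {
  for (s in 1:20) {
    preds <- random_prediction_table(n = 50 + 7 * s, seed = s)
    excl <- preds$ligand_id[seq_len(s)]
    expect_identical(
      sort(select_mixed(preds, excl, batch_size = 10,
                        pool_factor = 1)$ligand_id),
      sort(select_greedy(preds, excl, batch_size = 10)$ligand_id))
    expect_identical(
      select_mixed(preds, excl, batch_size = 10,
                   pool_factor = nrow(preds))$ligand_id,
      select_uncertain(preds, excl, batch_size = 10)$ligand_id)
  }
})

test_that("mixed selection equals an exhaustive two-stage sort", {
  preds <- tibble::tibble(
    ligand_id = LETTERS[1:10],
    mean_dg = c(-15, -14, -13.5, -13, -12, -11, -10, -9, -8, -7),
    uncertainty = c(0.1, 2, 0.5, 3, 1, 0.2, 5, 0.3, 0.4, 0.1))
  got <- select_mixed(preds, batch_size = 2, pool_factor = 3)
  # brute force: pool = 6 strongest, then 2 most uncertain among them
  pool <- preds[order(preds$mean_dg, preds$ligand_id), ][1:6, ]
  want <- pool[order(-pool$uncertainty, pool$ligand_id), ][1:2, ]
  expect_equal(got$ligand_id, want$ligand_id)
})

test_that("narrowing takes disjoint top lists as their union", {
  mk_pred <- function(ids, dg) {
    tibble::tibble(ligand_id = ids, mean_dg = dg, uncertainty = 1)
  }
  all_ids <- sprintf("L%02d", 1:40)
  ens <- list(a = structure(list(cv_rmse = 0.5), class = "al_ensemble"),
              b = structure(list(cv_rmse = 0.7), class = "al_ensemble"))
  # model a prefers L01..L20, model b prefers L21..L40
  preds <- list(a = mk_pred(all_ids, c(seq(-20, -15, length.out = 20),
                                       rep(-5, 20))),
                b = mk_pred(all_ids, c(rep(-5, 20),
                                       seq(-20, -15, length.out = 20))))
  batch <- select_narrowing(ens, preds, n_models = 2, per_model_top = 5)
  expect_setequal(batch$ligand_id,
                  c(sprintf("L%02d", 1:5), sprintf("L%02d", 21:25)))
  expect_equal(nrow(batch), 10L)
})

test_that("narrowing dedup follows round-robin next-best, as a brute force shows", {
  ids <- sprintf("L%02d", 1:30)
  dg <- seq(-20, -10, length.out = 30)
  pred <- tibble::tibble(ligand_id = ids, mean_dg = dg, uncertainty = 1)
  ens <- list(a = structure(list(cv_rmse = 0.4), class = "al_ensemble"),
              b = structure(list(cv_rmse = 0.6), class = "al_ensemble"))
  # identical prediction tables: second model must dig into ranks 21-40
  batch <- select_narrowing(ens, list(a = pred, b = pred),
                            n_models = 2, per_model_top = 10)
  # brute-force simulation of the dedup rule: alternate a, b; each takes
  # its next unclaimed rank
  taken <- character(0)
  pos <- c(a = 1, b = 1)
  ranked <- ids  # both models rank identically
  for (i in 1:10) {
    for (m in c("a", "b")) {
      while (ranked[pos[m]] %in% taken) pos[m] <- pos[m] + 1
      taken <- c(taken, ranked[pos[m]])
    }
  }
  expect_equal(batch$ligand_id, taken)
  expect_equal(nrow(batch), 20L)
  expect_false(anyDuplicated(batch$ligand_id) > 0)
})

test_that("narrowing errors when fewer ensembles than models requested", {
  ens <- list(a = structure(list(cv_rmse = 0.4), class = "al_ensemble"))
  expect_error(select_narrowing(ens, list(a = NULL), n_models = 5),
               "at least")
})

test_that("every strategy returns ids disjoint from the evaluated set", {
  for (s in 1:10) {
    preds <- random_prediction_table(80, seed = 200 + s)
    excl <- sample(preds$ligand_id, 30)
    for (fn in list(select_greedy, select_uncertain)) {
      expect_length(intersect(fn(preds, excl, 20)$ligand_id, excl), 0)
    }
    expect_length(intersect(select_mixed(preds, excl, 20, 2)$ligand_id,
                            excl), 0)
    expect_length(intersect(
      select_random(preds$ligand_id, excl, 20, seed = s)$ligand_id, excl), 0)
  }
})

test_that("degenerate single-bin weighting is uniform sampling", {
  n <- 100L
  coords <- tibble::tibble(ligand_id = sprintf("l%03d", 1:n),
                           dim1 = runif(n, 0, 0.9), dim2 = runif(n, 0, 0.9))
  lib <- tibble::tibble(ligand_id = coords$ligand_id)
  counts <- integer(n)
  names(counts) <- coords$ligand_id
  n_draws <- 40L
  for (s in seq_len(n_draws)) {
    b <- weighted_random_init(lib, coords, batch_size = 50, seed = s)
    counts[b$ligand_id] <- counts[b$ligand_id] + 1L
  }
  # >= 2000 inclusion draws; uniform inclusion if weighting is degenerate
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("inverse-bin-count weighting balances unequal bins", {
  n_big <- 900L
  n_small <- 100L
  coords <- tibble::tibble(
    ligand_id = sprintf("l%04d", seq_len(n_big + n_small)),
    dim1 = c(runif(n_big, 0, 0.9), runif(n_small, 5, 5.9)),
    dim2 = 0.5)
  lib <- tibble::tibble(ligand_id = coords$ligand_id)
  small_ids <- coords$ligand_id[(n_big + 1):(n_big + n_small)]
  picked_small <- vapply(1:200, function(s) {
    sum(weighted_random_init(lib, coords, batch_size = 10,
                             seed = s)$ligand_id %in% small_ids)
  }, numeric(1))
  # each bin should contribute about half the batch of 10
  expect_equal(mean(picked_small), 5, tolerance = 0.15)
})

test_that("weighted random initialization is reproducible under its seed", {
  coords <- tibble::tibble(ligand_id = sprintf("l%03d", 1:50),
                           dim1 = rnorm(50), dim2 = rnorm(50))
  lib <- tibble::tibble(ligand_id = coords$ligand_id)
  b1 <- weighted_random_init(lib, coords, batch_size = 10, seed = 3)
  b2 <- weighted_random_init(lib, coords, batch_size = 10, seed = 3)
  expect_identical(b1, b2)
  expect_equal(b1$iteration, rep(0L, 10))
})

test_that("library embedding yields finite seeded 2D coordinates", {
  blk <- feature_block(matrix(rnorm(150), 30, 5), sprintf("l%02d", 1:30),
                       name = "x")
  emb <- embed_library(blk, seed = 2)
  expect_equal(nrow(emb), 30L)
  expect_true(all(is.finite(emb$dim1)) && all(is.finite(emb$dim2)))
  expect_equal(embed_library(blk, seed = 2), emb)
})

test_that("policy schedules dispatch the documented strategy per iteration", {
  expect_equal(policy_schedule(0, "narrowing"), "weighted_random_init")
  expect_equal(policy_schedule(1, "narrowing"), "narrowing")
  expect_equal(policy_schedule(3, "narrowing"), "narrowing")
  expect_equal(policy_schedule(4, "narrowing"), "greedy")
  expect_equal(policy_schedule(1, "random2greedy"), "random")
  expect_equal(policy_schedule(4, "random2greedy"), "greedy")
  expect_equal(policy_schedule(2, "uncertain"), "uncertain")
  expect_error(policy_schedule(1, "bogus"), "unknown policy")
})
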