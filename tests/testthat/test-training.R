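test_that("configuration presets and variant constraints hold", {
  cfg <- foc_config("foc", preset = "desk", seed = 3)
  expect_equal(cfg$lambda_s, 1)
  expect_equal(cfg$lambda_u, 1)
  light <- foc_config("foc-light", preset = "desk")
  expect_equal(light$lambda_u, 0)
  expect_equal(light$warmup_epochs, 0L)
  expect_equal(light$repetitions, 1L)
  warm <- foc_config("warmup-only", preset = "desk")
  expect_equal(warm$lambda_s, 0)
  expect_equal(warm$main_epochs, 0L)
  paper <- foc_config("foc", preset = "paper")
  expect_equal(paper$warmup_epochs, 500L)
  expect_equal(paper$heads_only_epochs, 100L)
  expect_equal(paper$lr_heads_only, 1e-3)
  expect_equal(paper$lr_main, 1e-4)
  expect_error(foc_config("foc", nonsense_field = 1), "unknown config")
})

test_that("zero loss weights leave every parameter bitwise unchanged", {
  ds <- tiny_synce(24, 8, seed = 4)
  cfg <- micro_config(seed = 7, lambda_s = 0, lambda_u = 0)
  fit <- train_foc(ds, cfg)
  ref <- build_model(
    backbone_spec(input_size = cfg$input_size, channels = cfg$channels),
    list(head_config("normal", 6, cfg$head_copies),
         head_config("overclustering", cfg$k_over, cfg$head_copies)),
    k_gt = 6, seed = focr:::mix_seed(cfg$seed, 5L))
  expect_identical(fit$model$backbone$params, ref$backbone$params)
  for (h in seq_along(ref$heads))
    expect_identical(fit$model$heads[[h]]$W, ref$heads[[h]]$W)
})

test_that("warm-up trains with the unsupervised loss only", {
  ds <- tiny_synce(24, 8, seed = 4)
  fit <- warmup(ds, micro_config(seed = 1, warmup_epochs = 4L))
  expect_true(all(fit$log$phase == "warmup"))
  expect_true(all(fit$log$loss_s == 0))
  expect_true(any(fit$log$loss_u != 0))
  # the mutual-information objective improves on average over epochs
  lu <- fit$log$loss_u
  expect_lte(mean(tail(lu, 2)), mean(head(lu, 2)) + 0.05)
  expect_error(warmup(ds, foc_config("foc-light", preset = "desk")),
               "no warm-up")
})

test_that("a tiny model overfits a small certain training set", {
  ds <- synce_generate(32, 2, mode = "fuzzy", seed = 21)
  cfg <- foc_config("foc-light", preset = "desk", seed = 2,
                    input_size = 16L, channels = c(8L, 12L, 16L, 24L),
                    k_over = 12L, head_copies = 2L,
                    batch_size = 16L, batches_per_epoch = 2L,
                    heads_only_epochs = 2L, main_epochs = 50L,
                    val_max = 40L, eval_every = 5L,
                    augmentation = "identity")
  fit <- train_foc(ds, cfg)
  train_rows <- which(ds$manifest$split == "train" & ds$manifest$certain)
  probs <- predict_heads(fit$model, ds, train_rows)
  types <- attr(probs, "types")
  truth <- ds$manifest$hard_label[train_rows]
  acc <- max(vapply(which(types == "normal"), function(h)
    accuracy(max.col(probs[[h]], ties.method = "first"), truth),
    numeric(1)))
  expect_gte(acc, 0.95)
})

test_that("phases run in order with the configured learning rates", {
  ds <- tiny_synce(24, 8, seed = 4)
  cfg <- micro_config(seed = 3, warmup_epochs = 2L,
                      heads_only_epochs = 2L, main_epochs = 2L,
                      lr_warmup = 1e-3, lr_heads_only = 5e-3,
                      lr_main = 1e-4)
  fit <- train_foc(ds, cfg)
  expect_equal(fit$log$phase,
               c("warmup", "warmup", "heads_only", "heads_only",
                 "main", "main"))
  expect_equal(fit$log$lr, c(1e-3, 1e-3, 5e-3, 5e-3, 1e-4, 1e-4))
  # head types alternate every epoch
  expect_equal(fit$log$head_type,
               rep(c("normal", "overclustering"), 3))
  # foc-light has no warm-up phase in its trace
  light <- train_foc(ds, micro_config("foc-light", seed = 3,
                                      main_epochs = 2L))
  expect_false("warmup" %in% light$log$phase)
})

test_that("the heads-only phase leaves the backbone frozen", {
  ds <- tiny_synce(24, 8, seed = 4)
  cfg <- micro_config(seed = 11, warmup_epochs = 0L,
                      heads_only_epochs = 3L, main_epochs = 0L)
  fit <- train_foc(ds, cfg)
  ref <- build_model(
    backbone_spec(input_size = cfg$input_size, channels = cfg$channels),
    list(head_config("normal", 6, cfg$head_copies),
         head_config("overclustering", cfg$k_over, cfg$head_copies)),
    k_gt = 6, seed = focr:::mix_seed(cfg$seed, 5L))
  expect_identical(fit$model$backbone$params, ref$backbone$params)
  # the heads did move
  expect_false(identical(fit$model$heads[[1]]$W, ref$heads[[1]]$W))
})

test_that("training is reproducible from the seed", {
  ds <- tiny_synce(24, 8, seed = 4)
  f1 <- train_foc(ds, micro_config(seed = 5))
  f2 <- train_foc(ds, micro_config(seed = 5))
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$model$backbone$params, f2$model$backbone$params)
  f3 <- train_foc(ds, micro_config(seed = 6))
  expect_false(identical(f1$log$loss, f3$log$loss))
})
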