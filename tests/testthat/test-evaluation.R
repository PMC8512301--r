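test_that("accuracy is the micro-averaged correct-classification rate", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 1, 2), c(1, 2, 2)), 2 / 3)
  # micro-averaged F1 from summed confusion counts equals accuracy
  set.seed(6)
  pred <- sample(1:4, 200, replace = TRUE)
  truth <- sample(1:4, 200, replace = TRUE)
  tp <- sum(pred == truth)
  fp <- sum(pred != truth)   # every error is one FP and one FN
  micro_f1 <- 2 * tp / (2 * tp + fp + fp)
  expect_equal(accuracy(pred, truth), micro_f1)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
})

test_that("macro F1 averages per-class scores", {
  expect_equal(macro_f1(c(1, 2), c(1, 2), 2), 1)
  # per-class hand evaluation: F1(1) = 0.8, F1(2) = 2/3
  expect_equal(macro_f1(c(1, 1, 1, 2), c(1, 1, 2, 2), 2),
               mean(c(0.8, 2 / 3)))
  set.seed(2)
  pred <- sample(1:3, 60, replace = TRUE)
  truth <- sample(1:3, 60, replace = TRUE)
  perm <- sample(60)
  expect_equal(macro_f1(pred, truth, 3), macro_f1(pred[perm], truth[perm], 3))
  # a class absent everywhere contributes zero
  expect_equal(macro_f1(c(1, 1), c(1, 1), 2), 0.5)
})

test_that("majority mapping picks the dominant class with lowest-id ties", {
  expect_equal(majority_mapping(c(1, 1, 1), c(1, 1, 2), k = 1), 1L)
  expect_equal(majority_mapping(c(1, 1), c(2, 1), k = 1), 1L)  # tie
  mp <- majority_mapping(c(1, 1, 3), c(2, 2, 1), k = 3)
  expect_equal(mp, c(2L, NA, 1L))
  expect_equal(apply_mapping(mp, c(3, 1, 1)), c(1L, 2L, 2L))
})

test_that("majority mapping maximizes accuracy over all constant mappings", {
  set.seed(13)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    k_gt <- sample(2:3, 1)
    n <- sample(4:8, 1)
    cl <- sample(seq_len(k), n, replace = TRUE)
    tr <- sample(seq_len(k_gt), n, replace = TRUE)
    mp <- majority_mapping(cl, tr, k = k)
    acc_maj <- mean(mp[cl] == tr)
    # exhaustive enumeration of every cluster -> class assignment
    grid <- do.call(expand.grid, rep(list(seq_len(k_gt)), k))
    best <- max(apply(grid, 1, function(g) mean(g[cl] == tr)))
    expect_equal(acc_maj, best)
  }
})

test_that("consistency scores summarize expert judgments per cluster", {
  r <- consistency(rep(1, 10), c(rep(TRUE, 8), rep(FALSE, 2)))
  expect_equal(r$overall, 0.8)
  r2 <- consistency(c(1, 1, 2, 2), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(r2$per_cluster), c(1, 0.5))
  expect_equal(r2$mean, 0.75)
  # population standard deviation
  expect_equal(r2$sd, sqrt(mean((c(1, 0.5) - 0.75)^2)))
  r3 <- consistency(c(1, 2, 1), c(TRUE, TRUE, TRUE))
  expect_equal(r3$overall, 1)
  expect_equal(r3$sd, 0)
  # excluding a catch-all class
  r4 <- consistency(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE),
                    classes = c(1, 1, 9, 9), exclude_class = 9)
  expect_equal(r4$overall, 1)
  expect_error(consistency(1:3, c(TRUE, TRUE)), "equal length")
})

test_that("model evaluation composes mapping and metrics per head", {
  ds <- tiny_synce(24, 8, seed = 5)
  cfg <- micro_config(seed = 2)
  fit <- train_foc(ds, cfg)
  m <- evaluate_model(fit, ds, split = "unlabeled")
  expect_s3_class(m, "foc_metrics")
  expect_equal(nrow(m$heads), 4)
  expect_true(all(m$heads$macro_f1 >= 0 & m$heads$macro_f1 <= 1))
  expect_true(all(m$heads$accuracy >= 0 & m$heads$accuracy <= 1))
  expect_true(all(c("normal", "overclustering") %in% m$heads$type))
  expect_true(m$best %in% seq_len(4))
  # validation split works with an explicit mapping split
  mv <- evaluate_model(fit, ds, split = "validation",
                       mapping_split = "train")
  expect_equal(mv$split, "validation")
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(m, path)
  rep <- jsonlite::read_json(path)
  expect_equal(length(rep$heads), 4)
  expect_equal(rep$best_macro_f1, m$heads$macro_f1[m$best])
})

test_that("predictions and judgments round-trip through CSV", {
  ds <- tiny_synce(12, 4, seed = 8)
  m <- build_model(backbone_spec(input_size = 8, channels = c(3, 4, 4, 5)),
                   list(head_config("normal", 6, 1),
                        head_config("overclustering", 8, 1)),
                   k_gt = 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(m, ds, path, rows = 1:10)
  d <- read.csv(path)
  expect_equal(nrow(d), 20)  # 10 images x 2 heads
  expect_true(all(d$prediction >= 1))
  p_norm <- as.matrix(d[d$head == 1, paste0("p", 1:6)])
  expect_equal(unname(rowSums(p_norm)), rep(1, 10), tolerance = 1e-6)
  # judgments
  jpath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(filename = letters[1:4], cluster = c(1, 1, 2, 2),
                       consistent = c(TRUE, TRUE, TRUE, FALSE),
                       class = c(1, 1, 9, 9)),
            jpath, row.names = FALSE)
  r <- consistency_from_csv(jpath)
  expect_equal(r$overall, 0.75)
  expect_equal(consistency_from_csv(jpath, exclude_class = 9)$overall, 1)
})
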