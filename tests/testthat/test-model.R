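make_test_model <- function(seed = 9) {
  build_model(backbone_spec(input_size = 8, channels = c(3, 4, 4, 5)),
              list(head_config("normal", 6, 2),
                   head_config("overclustering", 8, 2)),
              k_gt = 6, seed = seed)
}

test_that("model construction validates head sizes and copies", {
  m <- make_test_model()
  expect_s3_class(m, "foc_model")
  expect_length(m$heads, 4)
  expect_error(build_model(backbone_spec(),
                           list(head_config("overclustering", 6)), 6),
               "k > k_gt")
  expect_error(build_model(backbone_spec(),
                           list(head_config("normal", 4)), 6),
               "normal heads")
  expect_error(head_config("normal", 6, copies = 0), "copies")
  # head copies are independently initialized
  expect_false(identical(m$heads[[1]]$W, m$heads[[2]]$W))
})

test_that("every head emits softmax probabilities and inference is deterministic", {
  m <- make_test_model()
  set.seed(1)
  imgs <- lapply(1:5, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  out <- model_forward(m, imgs)
  for (p in out$heads) {
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_equal(ncol(out$heads[[1]]), 6)
  expect_equal(ncol(out$heads[[3]]), 8)
  expect_identical(out$heads, model_forward(m, imgs)$heads)
})

test_that("best-head selection takes the maximum with lowest-index ties", {
  expect_equal(select_best_head(c(0.6, 0.8, 0.7)), 2)
  expect_equal(select_best_head(0.5), 1)
  expect_equal(select_best_head(c(0.8, 0.8)), 1)
  expect_error(select_best_head(numeric(0)), "empty")
})

test_that("backbone and loss gradients match finite differences", {
  eng <- asNamespace("focr")
  m <- make_test_model()
  set.seed(3)
  imgs <- lapply(1:12, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  plan <- data.frame(src1 = 1:6, src2 = c(7, 8, 9, 10, 5, 6),
                     src3 = c(11, 12, 7, 8, 1, 2),
                     supervised = c(rep(TRUE, 4), FALSE, FALSE),
                     y = c(1, 2, 3, 1, NA, NA),
                     y_prime = c(2, 3, 1, 2, NA, NA))
  w <- loss_weights(1, 1)
  h <- 1e-6
  for (ht in c("normal", "overclustering")) {
    hidx <- which(vapply(m$heads, `[[`, "", "type") == ht)
    g <- eng$batch_loss_grads(m, plan, imgs, hidx, w, eps = 1e-6,
                              policy = "identity")
    lossfn <- function(mm) eng$batch_loss_grads(
      mm, plan, imgs, hidx, w, 1e-6, "identity",
      need_backbone_grads = FALSE)$loss
    for (nm in c("W1", "W3")) {
      p <- m$backbone$params[[nm]]
      for (ii in sample(length(p), 4)) {
        mp <- m; mp$backbone$params[[nm]][ii] <- p[ii] + h
        mm <- m; mm$backbone$params[[nm]][ii] <- p[ii] - h
        num <- (lossfn(mp) - lossfn(mm)) / (2 * h)
        expect_equal(g$backbone_grads[[nm]][ii], num, tolerance = 1e-5)
      }
    }
    hh <- hidx[1]
    for (ii in sample(length(m$heads[[hh]]$W), 4)) {
      mp <- m; mp$heads[[hh]]$W[ii] <- m$heads[[hh]]$W[ii] + h
      mm <- m; mm$heads[[hh]]$W[ii] <- m$heads[[hh]]$W[ii] - h
      num <- (lossfn(mp) - lossfn(mm)) / (2 * h)
      expect_equal(g$head_grads[[as.character(hh)]]$W[ii], num,
                   tolerance = 1e-5)
    }
  }
})

test_that("sobel transform responds to edges with two channels", {
  img <- array(0, c(8, 8, 3))
  img[, 5:8, ] <- 1   # vertical edge
  s <- sobel_transform(img)
  expect_equal(dim(s), c(8, 8, 2))
  expect_gt(max(abs(s[, , 1])), 0.4)   # horizontal gradient fires
  expect_equal(max(abs(s[4, 2, 2])), 0)  # no vertical gradient inside
})

test_that("checkpoints round-trip through disk", {
  m <- make_test_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, config = list(note = "test"))
  ck <- load_checkpoint(path)
  set.seed(5)
  imgs <- lapply(1:3, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  expect_identical(model_forward(ck$model, imgs)$heads,
                   model_forward(m, imgs)$heads)
  expect_equal(ck$config$note, "test")
})
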