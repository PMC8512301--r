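test_that("color distribution interpolates linearly between primary hues", {
  expect_equal(unname(color_distribution(0)), c(1, 0, 0))
  expect_equal(unname(color_distribution(120)), c(0, 1, 0))
  expect_equal(unname(color_distribution(240)), c(0, 0, 1))
  expect_equal(unname(color_distribution(60)), c(0.5, 0.5, 0))
  # wrap segment: between blue and red
  expect_equal(unname(color_distribution(300)), c(0.5, 0, 0.5))
  set.seed(1)
  hues <- runif(50, 0, 360)
  pc <- color_distribution(hues)
  expect_equal(rowSums(pc), rep(1, 50))
  expect_true(all(pc >= 0))
  # exactly two adjacent primaries share the mass
  expect_true(all(rowSums(pc > 0) <= 2))
  expect_error(color_distribution(360), "hue")
  expect_error(color_distribution(-1), "hue")
})

test_that("geometry distribution interpolates circle to ellipse", {
  expect_equal(unname(geometry_distribution(1)), c(1, 0))
  expect_equal(unname(geometry_distribution(2)), c(0, 1))
  expect_equal(unname(geometry_distribution(1.5)), c(0.5, 0.5))
  expect_equal(unname(geometry_distribution(1.25)), c(0.75, 0.25))
  expect_error(geometry_distribution(0.9), "axis_ratio")
  expect_error(geometry_distribution(2.1), "axis_ratio")
})

test_that("fuzzy labels are the flattened outer product and sum to one", {
  l <- fuzzy_label(c(1, 0, 0), c(1, 0))
  expect_equal(unname(l), c(1, 0, 0, 0, 0, 0))
  expect_equal(names(l), synce_classes())
  l2 <- fuzzy_label(c(0.5, 0.5, 0), c(0.5, 0.5))
  expect_equal(unname(l2), c(0.25, 0.25, 0.25, 0.25, 0, 0))
  set.seed(42)
  for (i in 1:25) {
    hue <- runif(1, 0, 360)
    ratio <- runif(1, 1, 2)
    pc <- color_distribution(hue)
    pg <- geometry_distribution(ratio)
    l <- fuzzy_label(pc, pg)
    expect_equal(sum(l), 1, tolerance = 1e-9)
    expect_equal(unname(l), as.vector(t(outer(pc, pg))))
  }
  expect_error(fuzzy_label(c(0.7, 0.7, 0), c(1, 0)), "summing to 1")
})

test_that("rendered bubbles are deterministic shapes on black", {
  spec <- bubble_spec(0, 1, c(32, 32), 30, 0, 64)
  img <- render_bubble(spec)
  expect_equal(dim(img), c(64, 64, 3))
  # corners are background
  expect_equal(img[1, 1, ], c(0, 0, 0))
  expect_equal(img[64, 64, ], c(0, 0, 0))
  # circle: the mask extents along rows and columns agree within 1 px
  mask <- img[, , 1] > 0.5
  expect_lt(abs(diff(range(which(rowSums(mask) > 0))) -
                  diff(range(which(colSums(mask) > 0)))), 2)
  # determinism
  expect_identical(img, render_bubble(spec))
  # an ellipse twice as long as wide (axis-aligned)
  spec2 <- bubble_spec(240, 2, c(32, 32), 30, 0, 64)
  img2 <- render_bubble(spec2, antialias = FALSE)
  m2 <- img2[, , 3] > 0.5
  w <- diff(range(which(colSums(m2) > 0))) + 1
  h <- diff(range(which(rowSums(m2) > 0))) + 1
  expect_equal(w / h, 2, tolerance = 0.15)
  expect_error(bubble_spec(0, 1, c(2, 2), 30, 0, 64), "fit")
})

test_that("split generation honors counts, certainty and modes", {
  ds <- tiny_synce(30, 12, seed = 7)
  m <- ds$manifest
  tab <- table(m$split, m$certain)
  expect_true(all(tab[, "TRUE"] == 30))
  expect_true(all(tab[, "FALSE"] == 12))
  soft <- as.matrix(m[, paste0("l_", synce_classes())])
  expect_equal(rowSums(soft), rep(1, nrow(m)), tolerance = 1e-9)
  # certain iff one-hot iff anchor hue/ratio
  onehot <- apply(soft, 1, max) == 1
  expect_equal(onehot, m$certain)
  anchor <- m$hue %in% c(0, 120, 240) & m$axis_ratio %in% c(1, 2)
  expect_equal(anchor, m$certain)
  # fuzzy mode: labeled training rows are certain only
  lab <- m$split == "train" & !is.na(m$hard_label)
  expect_true(all(m$certain[lab]))
  expect_true(all(is.na(m$hard_label[m$split == "train" & !m$certain])))
  expect_true(all(is.na(m$hard_label[m$split == "unlabeled"])))
})

test_that("ideal mode assigns the most likely class as hard label", {
  ds <- tiny_synce(10, 20, mode = "ideal", seed = 3)
  m <- ds$manifest
  soft <- as.matrix(m[, paste0("l_", synce_classes())])
  lab <- m$split != "unlabeled"
  expect_equal(m$hard_label[lab],
               max.col(soft, ties.method = "first")[lab])
})

test_that("real mode samples hard labels from the fuzzy distribution", {
  ds <- synce_generate(10, 10000, mode = "real", seed = 5)
  m <- ds$manifest
  soft <- as.matrix(m[, paste0("l_", synce_classes())])
  rows <- which(m$split == "train" & !m$certain)
  ml <- max.col(soft, ties.method = "first")
  # law of large numbers: the rate at which the sampled label equals the
  # most likely class matches the mean maximal soft probability
  observed <- mean(m$hard_label[rows] == ml[rows])
  expected <- mean(apply(soft[rows, ], 1, max))
  expect_lt(abs(observed - expected), 0.02)
})

test_that("generation is reproducible from the seed and varies across seeds", {
  a <- tiny_synce(12, 6, seed = 11)
  b <- tiny_synce(12, 6, seed = 11)
  c <- tiny_synce(12, 6, seed = 12)
  expect_identical(a$manifest, b$manifest)
  expect_false(isTRUE(all.equal(a$manifest$hue, c$manifest$hue)))
  expect_identical(dataset_images(a, 1:3, size = 16),
                   dataset_images(b, 1:3, size = 16))
})

test_that("datasets round-trip through PNG + CSV on disk", {
  dir <- withr::local_tempdir()
  ds <- tiny_synce(8, 4, seed = 2)
  synce_write(ds, dir, render_size = 32)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_image_dataset(dir)
  expect_s3_class(back, "focr_dataset")
  expect_equal(back$classes, synce_classes())
  expect_equal(back$manifest$hard_label, ds$manifest$hard_label)
  expect_equal(back$manifest$split, ds$manifest$split)
  soft_cols <- paste0("l_", synce_classes())
  expect_equal(as.matrix(back$manifest[, soft_cols]),
               as.matrix(ds$manifest[, soft_cols]), tolerance = 1e-12)
  # the spec columns allow re-rendering without touching the PNGs
  expect_s3_class(back, "synce_dataset")
  img <- dataset_images(back, 1, size = 16)[[1]]
  expect_equal(dim(img), c(16, 16, 3))
  # writing twice gives byte-identical manifests
  dir2 <- withr::local_tempdir()
  synce_write(tiny_synce(8, 4, seed = 2), dir2, render_size = 32)
  expect_identical(readLines(file.path(dir, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
})
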