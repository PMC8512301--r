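#' @title Triplet data pipeline
#'
#' @description
#' Every training example is a triplet `(x1, x2, x3)` derived from one
#' source image `x`. For an unlabeled `x`, `x1` and `x2` are two
#' independent augmentations of `x` and `x3` is an augmentation of a
#' random other image from the full pool. For a labeled `x`, `x2` is an
#' augmentation of a *different* image sharing the label of `x` (a
#' "supervised augmentation" mocking an ideal label-preserving
#' transform) and `x3` is an augmentation of an image with a different
#' label (the inverse example). Batches bound the unlabeled fraction by
#' the ratio `r` and repeat each selected source image several times
#' with fresh augmentations.
#'
#' @name data_pipeline
NULL

#' Batch specification
#'
#' @param batch_size Images (triplets) per batch; must be a multiple of
#'   `repetitions`.
#' @param ratio Upper bound `r` on the unlabeled fraction per batch, in
#'   `[0, 1]`.
#' @param repetitions Consecutive re-augmented copies of every selected
#'   source image (default 3); stabilizes the batch estimate of the
#'   joint output distribution.
#' @return A `batch_spec` list.
#' @export
batch_spec <- function(batch_size = 60L, ratio = 0.5, repetitions = 3L) {
  if (ratio < 0 || ratio > 1) stop("`ratio` must be in [0, 1]")
  if (repetitions < 1L) stop("`repetitions` must be >= 1")
  if (batch_size < repetitions) stop("`batch_size` must be >= `repetitions`")
  if (batch_size %% repetitions != 0L)
    stop("`batch_size` must be a multiple of `repetitions`")
  structure(list(batch_size = as.integer(batch_size), ratio = ratio,
                 repetitions = as.integer(repetitions)),
            class = "batch_spec")
}

# deterministic sub-seed, kept well below 2^31
mix_seed <- function(seed, a = 0L, b = 0L) {
  (as.integer(seed) %% 65011L) * 33013L + a * 257L + b
}

# source indices for one triplet, given the label context; draws from
# the global RNG
triplet_sources <- function(i, label, labels_labeled, labeled_pool,
                            full_pool) {
  if (!is.na(label)) {
    same <- labeled_pool[labels_labeled == label & labeled_pool != i]
    x2 <- if (length(same)) same[sample.int(length(same), 1L)] else i
    other <- which(labels_labeled != label)
    if (!length(other))
      stop("cannot draw an inverse example: only one class in the labeled pool")
    j <- other[sample.int(length(other), 1L)]
    list(src2 = x2, src3 = labeled_pool[j], y = label,
         y_prime = labels_labeled[j], supervised = TRUE)
  } else {
    pool <- full_pool[full_pool != i]
    list(src2 = i, src3 = pool[sample.int(length(pool), 1L)],
         y = NA_integer_, y_prime = NA_integer_, supervised = FALSE)
  }
}

#' Build one training triplet
#'
#' @param x A sample: list with `image` (array) and `label` (1-based
#'   class index or `NA`).
#' @param labeled_pool List of labeled samples (each with `image` and
#'   `label`); must contain at least two classes when `x` is labeled.
#' @param full_pool List of all samples (labeled and unlabeled).
#' @param policy Augmentation policy name.
#' @return A `triplet`: list with images `x1`, `x2`, `x3`, the
#'   `supervised` flag, and (when supervised) labels `y` and `y_prime`
#'   with `y != y_prime`.
#' @export
make_triplet <- function(x, labeled_pool, full_pool, policy = "default") {
  labels <- vapply(labeled_pool, function(s) as.integer(s$label), 0L)
  if (!is.null(x$label) && !is.na(x$label)) {
    same <- which(labels == x$label)
    same <- same[vapply(labeled_pool[same], function(s)
      !identical(s$image, x$image), TRUE)]
    x2src <- if (length(same))
      labeled_pool[[same[sample.int(length(same), 1L)]]]$image else x$image
    other <- which(labels != x$label)
    if (!length(other))
      stop("cannot draw an inverse example: only one class in the labeled pool")
    j <- other[sample.int(length(other), 1L)]
    structure(list(x1 = augment(x$image, policy),
                   x2 = augment(x2src, policy),
                   x3 = augment(labeled_pool[[j]]$image, policy),
                   supervised = TRUE, y = x$label, y_prime = labels[j]),
              class = "triplet")
  } else {
    pool <- Filter(function(s) !identical(s$image, x$image), full_pool)
    x3src <- pool[[sample.int(length(pool), 1L)]]$image
    structure(list(x1 = augment(x$image, policy),
                   x2 = augment(x$image, policy),
                   x3 = augment(x3src, policy),
                   supervised = FALSE, y = NA_integer_,
                   y_prime = NA_integer_),
              class = "triplet")
  }
}

#' Assemble the batches of one epoch
#'
#' Selection is a seeded rotation: both pools are shuffled once
#' (deterministically from `seed`) and consumed round-robin across
#' epochs, so every unlabeled image is eventually seen even though each
#' batch carries at most `floor(ratio * batch_size)` unlabeled images.
#' Each selected source appears `repetitions` times consecutively; the
#' copies are re-augmented independently at training time.
#'
#' @param labeled Integer indices of the labeled pool (manifest rows).
#' @param unlabeled Integer indices of the unlabeled pool (may be
#'   empty).
#' @param labels 1-based class labels aligned with `labeled`.
#' @param spec A [batch_spec()].
#' @param seed Dataset-level integer seed.
#' @param epoch 1-based epoch index.
#' @param n_batches Batches in the epoch; default covers the labeled
#'   pool once.
#' @return List of batch plans, each a data.frame with columns `src1`,
#'   `src2`, `src3`, `supervised`, `y`, `y_prime` (one row per triplet,
#'   `batch_size` rows).
#' @export
assemble_batches <- function(labeled, unlabeled, labels, spec,
                             seed = 1L, epoch = 1L, n_batches = NULL) {
  stopifnot(inherits(spec, "batch_spec"))
  if (!length(labeled)) stop("labeled pool must be non-empty")
  slots <- spec$batch_size %/% spec$repetitions
  n_unl <- if (length(unlabeled)) floor(slots * spec$ratio) else 0L
  n_lab <- slots - n_unl
  if (n_lab < 1L) stop("`ratio` leaves no labeled slot per batch")
  if (is.null(n_batches)) n_batches <- ceiling(length(labeled) / n_lab)

  set.seed(mix_seed(seed, 1L))
  perm_l <- sample(labeled)
  perm_u <- if (length(unlabeled)) sample(unlabeled) else integer(0)
  take <- function(perm, offset, n) {
    if (!n) return(integer(0))
    perm[(offset + seq_len(n) - 1L) %% length(perm) + 1L]
  }
  lab_sel <- take(perm_l, (epoch - 1L) * n_batches * n_lab,
                  n_batches * n_lab)
  unl_sel <- take(perm_u, (epoch - 1L) * n_batches * n_unl,
                  n_batches * n_unl)

  set.seed(mix_seed(seed, 2L, epoch))
  full_pool <- c(labeled, unlabeled)
  lab_lookup <- match(lab_sel, labeled)
  lapply(seq_len(n_batches), function(b) {
    li <- lab_sel[((b - 1L) * n_lab + 1L):(b * n_lab)]
    ly <- labels[lab_lookup[((b - 1L) * n_lab + 1L):(b * n_lab)]]
    ui <- if (n_unl) unl_sel[((b - 1L) * n_unl + 1L):(b * n_unl)] else integer(0)
    srcs <- c(li, ui)
    labs <- c(ly, rep(NA_integer_, length(ui)))
    m <- length(srcs)
    src2 <- src3 <- yp <- integer(m)
    for (j in seq_len(m)) {
      tr <- triplet_sources(srcs[j], labs[j], labels, labeled, full_pool)
      src2[j] <- tr$src2
      src3[j] <- tr$src3
      yp[j] <- tr$y_prime
    }
    rep_idx <- rep(seq_len(m), each = spec$repetitions)
    data.frame(src1 = srcs[rep_idx], src2 = src2[rep_idx],
               src3 = src3[rep_idx], supervised = !is.na(labs[rep_idx]),
               y = labs[rep_idx], y_prime = yp[rep_idx])
  })
}
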