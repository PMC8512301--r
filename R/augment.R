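#' @title Augmentation policies
#'
#' @description
#' Named, label-preserving stochastic image transforms. Policies draw
#' from R's global RNG, so augmentation is reproducible whenever the
#' caller seeds the stream. The default policy combines a random crop
#' with independent side fractions (changing scale and mildly
#' distorting aspect ratio, as in the usual random-resized-crop), a
#' horizontal flip, a small hue rotation (+-30 degrees) and a
#' multiplicative brightness jitter. The hue and aspect jitters matter
#' for calibration: they force the class boundary learned from anchor
#' examples towards the perceptual midpoint instead of a
#' feature-presence threshold.
#'
#' @name augmentation
NULL

.aug_registry <- new.env(parent = emptyenv())

#' Register an augmentation policy
#'
#' @param name Policy name.
#' @param fn Function `(img) -> img` mapping an `H x W x C` array to an
#'   array of the same shape; may use the global RNG.
#' @export
register_augmentation <- function(name, fn) {
  assign(name, fn, envir = .aug_registry)
  invisible(name)
}

#' Apply an augmentation policy
#'
#' @param x `H x W x C` image array in `[0, 1]`.
#' @param policy Registered policy name (`"default"`, `"identity"`,
#'   `"flip"`, or user-registered).
#' @return Augmented image of the same shape.
#' @export
augment <- function(x, policy = "default") {
  fn <- get0(policy, envir = .aug_registry)
  if (is.null(fn)) stop("unknown augmentation policy: ", policy)
  fn(x)
}

aug_flip <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

# random crop with independent row/column fractions: changes scale and
# aspect ratio, the usual random-resized-crop distortion. The range
# allows aspect distortion up to ~1.18, which keeps anchor shapes on
# their side of the circle/ellipse midpoint while forcing the learned
# boundary towards it.
aug_crop <- function(img, lo = 0.85, hi = 1) {
  s <- dim(img)[1]
  ci <- max(1L, round(s * runif(1, lo, hi)))
  cj <- max(1L, round(s * runif(1, lo, hi)))
  if (ci == s && cj == s) return(img)
  oi <- sample.int(s - ci + 1L, 1L)
  oj <- sample.int(s - cj + 1L, 1L)
  crop <- img[oi:(oi + ci - 1L), oj:(oj + cj - 1L), , drop = FALSE]
  idx_i <- pmax(1L, ceiling(seq_len(s) * ci / s))
  idx_j <- pmax(1L, ceiling(seq_len(s) * cj / s))
  crop[idx_i, idx_j, , drop = FALSE]
}

aug_brightness <- function(img, lo = 0.85, hi = 1.15) {
  pmin(img * runif(1, lo, hi), 1)
}

# branch-free HSV -> RGB, vectorized over pixels
hsv_to_rgb <- function(h, s, v) {
  f <- function(n) {
    k <- (n + h * 6) %% 6
    v - v * s * pmax(0, pmin(k, 4 - k, 1))
  }
  cbind(f(5), f(3), f(1))
}

# rotate the hue of every pixel by `delta` degrees, keeping saturation
# and value; black pixels are untouched and skipped
aug_hue_rotate <- function(img, delta) {
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  sel <- which(m[, 1] + m[, 2] + m[, 3] > 0)
  if (!length(sel)) return(img)
  hsvm <- grDevices::rgb2hsv(t(m[sel, , drop = FALSE]), maxColorValue = 1)
  m[sel, ] <- hsv_to_rgb(hsvm[1, ] + delta / 360, hsvm[2, ], hsvm[3, ])
  array(m, d)
}

aug_default <- function(img) {
  img <- aug_crop(img)
  if (runif(1) < 0.5) img <- aug_flip(img)
  if (dim(img)[3] == 3L) img <- aug_hue_rotate(img, runif(1, -30, 30))
  aug_brightness(img)
}

# label-safe variant for datasets whose hard labels lie close to class
# boundaries (e.g. most-likely-class labels on ambiguous images): no
# aspect distortion and only a small hue rotation, so augmentation can
# not push an image across the boundary its label came from
aug_mild <- function(img) {
  f <- runif(1, 0.85, 1)
  s <- dim(img)[1]
  ci <- max(1L, round(s * f))
  if (ci < s) {
    oi <- sample.int(s - ci + 1L, 1L)
    oj <- sample.int(s - ci + 1L, 1L)
    img <- resize_image(img[oi:(oi + ci - 1L), oj:(oj + ci - 1L), ,
                            drop = FALSE], s)
  }
  if (runif(1) < 0.5) img <- aug_flip(img)
  if (dim(img)[3] == 3L) img <- aug_hue_rotate(img, runif(1, -8, 8))
  aug_brightness(img)
}

register_augmentation("identity", identity)
register_augmentation("flip", aug_flip)
register_augmentation("default", aug_default)
register_augmentation("mild", aug_mild)

# Fused augmentation + stacking for the training hot path: applies the
# geometric part (crop/flip) per image, then the color part (hue
# rotation, brightness) vectorized across the whole stacked batch.
# Draws the same kinds of jitter as the "default"/"mild" policies;
# only those two policies are eligible.
augment_stack <- function(images, idx, policies) {
  n <- length(idx)
  d <- dim(images[[idx[1]]])
  s <- d[1]
  hw <- s * s
  mild <- policies == "mild"
  ri <- matrix(0L, s, n)
  cjm <- matrix(0L, s, n)
  for (t in seq_len(n)) {
    lo <- 0.85
    ci <- max(1L, round(s * runif(1, lo, 1)))
    cj <- if (mild[t]) ci else max(1L, round(s * runif(1, lo, 1)))
    oi <- if (ci < s) sample.int(s - ci + 1L, 1L) else 1L
    oj <- if (cj < s) sample.int(s - cj + 1L, 1L) else 1L
    cjx <- oj - 1L + pmax(1L, ceiling(seq_len(s) * cj / s))
    if (runif(1) < 0.5) cjx <- rev(cjx)
    ri[, t] <- oi - 1L + pmax(1L, ceiling(seq_len(s) * ci / s))
    cjm[, t] <- cjx
  }
  X <- gather_stack(images, idx, ri, cjm, d[3])
  if (d[3] == 3L) {
    amp <- ifelse(mild, 8, 30)
    deltas <- runif(n, -amp, amp)
    sel <- which(X[, 1] + X[, 2] + X[, 3] > 0)
    if (length(sel)) {
      hsvm <- grDevices::rgb2hsv(t(X[sel, , drop = FALSE]),
                                 maxColorValue = 1)
      drow <- rep.int(deltas, rep.int(hw, n))[sel]
      X[sel, ] <- hsv_to_rgb(hsvm[1, ] + drow / 360, hsvm[2, ], hsvm[3, ])
    }
  }
  bright <- rep.int(runif(n, 0.85, 1.15), rep.int(hw, n))
  X <- X * bright
  X[X > 1] <- 1
  X
}
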