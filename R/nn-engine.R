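# Compact CPU engine for the small convolutional backbone and the
# linear softmax heads. Batches are kept in a "flat" layout: a matrix
# with N*H*W rows (column-major spatial order within each image, images
# stacked) and one column per channel. im2col/col2im and pooling are
# compiled (src/tensor_ops.cpp); every matrix product goes through BLAS.

# He-scaled initialization for a 3x3 conv expressed as a
# (9*Cin + 1, Cout) weight matrix whose last row is the bias; the
# column-block layout matches im2col3(..., ones = TRUE), so the bias
# rides along in the matrix product.
init_conv <- function(c_in, c_out) {
  rbind(matrix(rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
               9 * c_in, c_out),
        0)
}

# Four 3x3 conv layers (ReLU), 2x2 pooling after the first three,
# flattened (or globally averaged) features after the last.
# input_size must be divisible by 8.
init_backbone <- function(spec) {
  ch <- c(spec$in_channels, spec$channels)
  if (length(spec$channels) != 4L)
    stop("the test backbone uses exactly 4 conv layers")
  if (spec$input_size %% 8L != 0L)
    stop("`input_size` must be divisible by 8")
  params <- list()
  for (l in 1:4)
    params[[paste0("W", l)]] <- init_conv(ch[l], ch[l + 1])
  list(spec = spec, params = params)
}

add_bias <- function(A, b) {
  for (j in seq_along(b)) A[, j] <- A[, j] + b[j]
  A
}

# X: flat batch (N*S*S, in_channels). Returns features (N, F) and the
# cache needed for the backward pass.
backbone_forward <- function(bb, X, N, keep_cache = TRUE) {
  p <- bb$params
  H <- bb$spec$input_size
  maxpool <- !identical(bb$spec$pooling, "avg")
  cache <- vector("list", 4)
  Z <- X
  for (l in 1:4) {
    Xcol <- im2col3(Z, H, H, N, ones = TRUE)
    A <- Xcol %*% p[[paste0("W", l)]]
    mask <- A > 0
    Z <- A * mask
    if (keep_cache) cache[[l]] <- list(Xcol = Xcol, mask = mask, H = H)
    if (l < 4) {
      if (maxpool) {
        mp <- maxpool2_fw(Z, H, H, N)
        Z <- mp$out
        if (keep_cache) cache[[l]]$argmax <- mp$argmax
      } else {
        Z <- avgpool2_fw(Z, H, H, N)
      }
      H <- H %/% 2L
    }
  }
  if (identical(bb$spec$final, "gap")) {
    feats <- rowsum(Z, rep(seq_len(N), each = H * H), reorder = FALSE) / (H * H)
  } else {
    # flatten the H x H x C map per image into one feature vector
    feats <- array(Z, c(H * H, N, ncol(Z)))
    feats <- matrix(aperm(feats, c(2L, 1L, 3L)), N, H * H * ncol(Z))
  }
  list(features = feats,
       cache = if (keep_cache) list(layers = cache, N = N, H_last = H,
                                    C_last = ncol(Z)))
}

# dF: gradient w.r.t. features (N, F). Returns gradients with the same
# shapes as the backbone parameters.
backbone_backward <- function(bb, cache, dF) {
  p <- bb$params
  N <- cache$N
  H <- cache$H_last
  if (identical(bb$spec$final, "gap")) {
    dZ <- dF[rep(seq_len(N), each = H * H), , drop = FALSE] / (H * H)
  } else {
    dZ <- array(dF, c(N, H * H, cache$C_last))
    dZ <- matrix(aperm(dZ, c(2L, 1L, 3L)), N * H * H, cache$C_last)
  }
  grads <- list()
  for (l in 4:1) {
    cl <- cache$layers[[l]]
    dA <- dZ * cl$mask
    grads[[paste0("W", l)]] <- crossprod(cl$Xcol, dA)
    if (l > 1) {
      W <- p[[paste0("W", l)]]
      c_in <- (nrow(W) - 1L) %/% 9L
      dXcol <- dA %*% t(W[-nrow(W), , drop = FALSE])
      dZ <- col2im3(dXcol, cl$H, cl$H, N, c_in)
      Hprev <- cache$layers[[l - 1]]$H
      am <- cache$layers[[l - 1]]$argmax
      dZ <- if (is.null(am)) avgpool2_bw(dZ, Hprev, Hprev, N)
        else maxpool2_bw(dZ, am, Hprev, Hprev, N)
    }
  }
  grads
}

# heads -----------------------------------------------------------------

init_head <- function(n_features, k) {
  list(W = matrix(rnorm(n_features * k, sd = sqrt(1 / n_features)),
                  n_features, k),
       b = numeric(k))
}

softmax_rows <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}

head_forward <- function(head, feats) {
  softmax_rows(add_bias(feats %*% head$W, head$b))
}

# Jacobian-vector product of the row-wise softmax: given probabilities
# q and the gradient g w.r.t. q, the gradient w.r.t. the logits is
# q * (g - rowSums(g * q)).
softmax_backward <- function(q, g) {
  q * (g - rowSums(g * q))
}

# Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# Updates `params` in place semantics: returns list(params, state).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
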