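#' @title Loss functions
#'
#' @description
#' The three loss components of the framework and their weighted
#' combination: standard cross-entropy for normal heads, inverse
#' cross-entropy for overclustering heads, and a mutual-information
#' objective over the batch joint distribution of two output views.
#' All losses follow a "lower is better" contract; mutual information is
#' therefore consumed negated.
#'
#' @name losses
NULL

check_prob <- function(p, arg, tol = 1e-6) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol * length(p))
    stop("`", arg, "` must be a probability vector summing to 1")
}

#' Cross-entropy
#'
#' `-sum(p_true * log(q_pred))` with the log clamped below at `eps`.
#'
#' @param p_true True distribution, or a single 1-based class index.
#' @param q_pred Predicted probability vector.
#' @param eps Clamp for the logarithm (default `1e-6`).
#' @return Non-negative scalar (nats).
#' @export
cross_entropy <- function(p_true, q_pred, eps = 1e-6) {
  if (length(p_true) == 1L && p_true == round(p_true)) {
    if (p_true < 1 || p_true > length(q_pred))
      stop("class index out of range")
    return(-log(max(q_pred[p_true], eps)))
  }
  if (length(p_true) != length(q_pred))
    stop("`p_true` and `q_pred` must have the same length")
  -sum(p_true * log(pmax(q_pred, eps)))
}

#' Inverse cross-entropy
#'
#' `CE^-1(p, q) = -sum_c p(c) * log(1 - q(c))`: the cross-entropy of `p`
#' against the *unnormalized* inverse distribution `1 - q`. It is zero
#' exactly when `p` and `q` put mass on disjoint classes, and it is used
#' to push the outputs of examples known to belong to different classes
#' into disjoint clusters. `1 - q` is deliberately not renormalized into
#' a distribution: renormalizing would penalize correct behavior (a
#' prediction split over several admissible clusters), would minimize
#' the entropy of `p`, and is unnecessary.
#'
#' @param p,q Probability vectors of equal length.
#' @param eps Clamp: `1 - q(c)` is bounded below by `eps` inside the log.
#' @return Non-negative scalar (nats).
#' @examples
#' inverse_cross_entropy(c(0.5, 0.5, 0), c(0, 0, 1))  # 0: disjoint support
#' @export
inverse_cross_entropy <- function(p, q, eps = 1e-6) {
  if (length(p) != length(q))
    stop("`p` and `q` must have the same length")
  if (eps <= 0 || eps > 1e-3) stop("`eps` must be in (0, 1e-3]")
  -sum(p * log(pmax(1 - q, eps)))
}

#' Inverse cross-entropy of a triplet
#'
#' The supervised loss of an overclustering head for one triplet
#' `(x1, x2, x3)` where `x3` is the inverse example:
#' `0.5 * CE^-1(out1, out3) + 0.5 * CE^-1(out2, out3)`.
#'
#' @param out1,out2 Head outputs for the two same-class views.
#' @param out3 Head output for the inverse example.
#' @param eps Clamp passed to [inverse_cross_entropy()].
#' @return Non-negative scalar, symmetric in `out1` and `out2`.
#' @export
ce_inverse_triplet <- function(out1, out2, out3, eps = 1e-6) {
  0.5 * inverse_cross_entropy(out1, out3, eps) +
    0.5 * inverse_cross_entropy(out2, out3, eps)
}

#' Batch joint distribution of two output views
#'
#' Estimates the joint distribution of the cluster variables behind two
#' sets of head outputs by averaging the outer products over the batch
#' and symmetrizing: `Q = mean_i outer(a_i, b_i)`, `P = (Q + t(Q)) / 2`.
#'
#' @param outputs_a,outputs_b Numeric matrices `n x k` of softmax
#'   outputs (rows are samples), or single probability vectors.
#' @return Symmetric `k x k` matrix with non-negative entries summing
#'   to 1.
#' @export
joint_distribution <- function(outputs_a, outputs_b) {
  if (is.null(dim(outputs_a))) outputs_a <- matrix(outputs_a, 1)
  if (is.null(dim(outputs_b))) outputs_b <- matrix(outputs_b, 1)
  if (!all(dim(outputs_a) == dim(outputs_b)))
    stop("`outputs_a` and `outputs_b` must have matching dimensions")
  if (nrow(outputs_a) < 1L) stop("empty batch")
  q <- crossprod(outputs_a, outputs_b) / nrow(outputs_a)
  (q + t(q)) / 2
}

#' Mutual information of a joint distribution
#'
#' `I(z, z') = sum_cc' P[c, c'] * log(P[c, c'] / (Pr[c] * Pc[c']))` with
#' the marginals as row/column sums, `0 * log(0)` treated as 0 and all
#' logs clamped at `eps`.
#'
#' @param P Joint distribution matrix (entries non-negative, summing
#'   to 1).
#' @param eps Clamp inside the logarithms.
#' @return Scalar in `[0, log k]` (up to clamping error).
#' @export
mutual_information <- function(P, eps = 1e-6) {
  if (abs(sum(P) - 1) > 1e-6 || any(P < -1e-9))
    stop("`P` must be a joint distribution (non-negative, sums to 1)")
  pr <- rowSums(P)
  pc <- colSums(P)
  terms <- P * (log(pmax(P, eps)) - log(pmax(outer(pr, pc), eps)))
  terms[P == 0] <- 0
  sum(terms)
}

#' Mutual-information loss for two batches of head outputs
#'
#' Convenience wrapper: the negated mutual information of
#' [joint_distribution()] of the two views, so that minimizing the loss
#' maximizes the mutual information.
#'
#' @inheritParams joint_distribution
#' @param eps Clamp passed to [mutual_information()].
#' @return Scalar loss (lower is better).
#' @export
mi_loss <- function(outputs_a, outputs_b, eps = 1e-6) {
  -mutual_information(joint_distribution(outputs_a, outputs_b), eps)
}

#' Loss weights
#'
#' @param lambda_s Weight of the supervised loss (default 1).
#' @param lambda_u Weight of the unsupervised loss (default 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_s = 1, lambda_u = 1) {
  if (lambda_s < 0 || lambda_u < 0) stop("loss weights must be >= 0")
  structure(list(lambda_s = lambda_s, lambda_u = lambda_u),
            class = "loss_weights")
}

#' Weighted combination of supervised and unsupervised loss
#'
#' `L = lambda_s * Ls + lambda_u * Lu`. `Ls` is cross-entropy for normal
#' heads and inverse cross-entropy for overclustering heads; `Lu` is the
#' negated mutual information. `lambda_s = 0` is the unsupervised
#' warm-up configuration; `lambda_u = 0` the light variant.
#'
#' @param Ls Supervised loss value.
#' @param Lu Unsupervised loss value.
#' @param weights A [loss_weights()].
#' @return Scalar.
#' @export
combined_loss <- function(Ls, Lu, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$lambda_s * Ls + weights$lambda_u * Lu
}
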