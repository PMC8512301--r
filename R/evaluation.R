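#' @title Evaluation metrics
#'
#' @description
#' Classification metrics for both head types. Normal heads are scored
#' directly; overclustering heads are first reduced to classes via a
#' majority-vote mapping from clusters to ground-truth classes, then
#' scored with the same metrics. Macro F1 is the headline metric for
#' fuzzy datasets because of their skewed class distributions.
#'
#' @name evaluation
NULL

#' Accuracy
#'
#' Fraction of correct predictions. Computed from the summed per-class
#' confusion counts (micro averaging), this equals the micro-averaged
#' F1 score.
#'
#' @param predictions,truths Equal-length vectors of class ids.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths))
    stop("`predictions` and `truths` must be non-empty and equal length")
  mean(predictions == truths)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of the per-class F1 scores
#' `F1 = 2*TP / (2*TP + FP + FN)`. A class absent from both predictions
#' and truths has an undefined F1 and contributes 0 (a conservative
#' convention under skewed class distributions).
#'
#' @param predictions,truths Equal-length vectors of 1-based class ids.
#' @param k Number of ground-truth classes.
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(predictions, truths, k) {
  if (!length(predictions) || length(predictions) != length(truths))
    stop("`predictions` and `truths` must be non-empty and equal length")
  f1 <- vapply(seq_len(k), function(c) {
    tp <- sum(predictions == c & truths == c)
    fp <- sum(predictions == c & truths != c)
    fn <- sum(predictions != c & truths == c)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Majority-vote cluster-to-class mapping
#'
#' Maps every non-empty cluster to its most frequent ground-truth class
#' on the reference data; ties are broken towards the lowest class id,
#' empty clusters are unmapped (`NA`) and excluded from metrics. Among
#' all per-cluster-constant label assignments this mapping maximizes
#' the post-mapping accuracy.
#'
#' @param cluster_assignments 1-based cluster ids.
#' @param truths 1-based ground-truth class ids, same length.
#' @param k Number of clusters (default: largest id observed).
#' @return Integer vector of length `k`: class id per cluster, `NA` for
#'   empty clusters.
#' @export
majority_mapping <- function(cluster_assignments, truths,
                             k = max(cluster_assignments)) {
  if (!length(cluster_assignments) ||
      length(cluster_assignments) != length(truths))
    stop("inputs must be non-empty and of equal length")
  if (any(cluster_assignments > k)) stop("cluster id exceeds `k`")
  vapply(seq_len(k), function(cl) {
    t_cl <- truths[cluster_assignments == cl]
    if (!length(t_cl)) return(NA_integer_)
    # which.max takes the first maximum, so ties resolve to the lowest id
    which.max(tabulate(t_cl))
  }, integer(1))
}

#' Apply a cluster-to-class mapping
#'
#' @param mapping Integer vector from [majority_mapping()].
#' @param cluster_assignments 1-based cluster ids.
#' @return Class ids (`NA` where the cluster is unmapped).
#' @export
apply_mapping <- function(mapping, cluster_assignments) {
  mapping[cluster_assignments]
}

#' Cluster consistency score
#'
#' An image is *consistent* if an expert judged it visually similar to
#' the majority of its predicted cluster. The overall consistency is
#' the number of consistent images divided by all images; per-cluster
#' ratios are summarized by their mean and population standard
#' deviation. Judgments are data (e.g. read from a rating CSV); they
#' are never simulated.
#'
#' @param cluster_assignments 1-based cluster ids.
#' @param judgments Logical vector: consistent or not, per image.
#' @param classes Optional class id per image, used with
#'   `exclude_class`.
#' @param exclude_class Optional class id whose images are dropped
#'   before scoring (e.g. a catch-all "no fit" class).
#' @return A `consistency_report`: list with `overall`, `per_cluster`
#'   (named ratios of non-empty clusters), `mean` and `sd`.
#' @export
consistency <- function(cluster_assignments, judgments, classes = NULL,
                        exclude_class = NULL) {
  if (length(cluster_assignments) != length(judgments))
    stop("inputs must have equal length")
  keep <- rep(TRUE, length(judgments))
  if (!is.null(exclude_class)) {
    if (is.null(classes)) stop("`classes` needed to exclude a class")
    keep <- classes != exclude_class
  }
  cl <- cluster_assignments[keep]
  jd <- as.logical(judgments[keep])
  per <- vapply(split(jd, cl), mean, numeric(1))
  structure(list(overall = mean(jd), per_cluster = per,
                 mean = mean(per),
                 sd = sqrt(mean((per - mean(per))^2))),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency: overall %.3f, per cluster %.3f +/- %.3f (%d clusters)\n",
              x$overall, x$mean, x$sd, length(x$per_cluster)))
  invisible(x)
}

# ground truth of a split: hard labels when present, otherwise the most
# likely class of the soft label
split_truths <- function(dataset, rows) {
  man <- dataset$manifest
  soft_cols <- paste0("l_", dataset$classes)
  if (all(soft_cols %in% names(man)))
    return(max.col(as.matrix(man[rows, soft_cols]), ties.method = "first"))
  tr <- man$hard_label[rows]
  if (anyNA(tr)) stop("split has no ground truth available")
  tr
}

#' Evaluate a trained model on a dataset split
#'
#' Computes accuracy and macro F1 per head on the requested split.
#' Overclustering heads are mapped to classes by majority vote on the
#' mapping split first: by default the unlabeled split maps on itself
#' (the protocol for fuzzy datasets, where experts would inspect the
#' unlabeled clusters), while other splits map on the training data.
#' Ground truth is the most likely class of the soft label when soft
#' labels are available, otherwise the hard label.
#'
#' @param fit A `foc_fit` (its best validation model is used) or a
#'   `foc_model`.
#' @param dataset A `focr_dataset`.
#' @param split Split to evaluate (default `"unlabeled"`).
#' @param mapping_split Split on which the cluster-to-class mapping is
#'   computed (default as described above).
#' @return A `foc_metrics` list: data.frame `heads` (type, accuracy,
#'   macro_f1, validation score when known), `best` (row index of the
#'   head selected by validation score, falling back to the evaluated
#'   metric), and `split`.
#' @export
evaluate_model <- function(fit, dataset, split = "unlabeled",
                           mapping_split = NULL) {
  model <- if (inherits(fit, "foc_fit")) fit$best_model else fit
  val_scores <- if (inherits(fit, "foc_fit")) fit$val_scores
  if (is.null(mapping_split))
    mapping_split <- if (split == "unlabeled") "unlabeled" else "train"
  man <- dataset$manifest
  rows <- which(man$split == split)
  if (!length(rows)) stop("no rows in split: ", split)
  k_gt <- length(dataset$classes)
  truths <- split_truths(dataset, rows)
  probs <- predict_heads(model, dataset, rows)
  types <- attr(probs, "types")
  if (identical(mapping_split, split)) {
    map_cl <- probs
    map_truths <- truths
  } else {
    map_rows <- which(man$split == mapping_split)
    map_cl <- predict_heads(model, dataset, map_rows)
    map_truths <- split_truths(dataset, map_rows)
  }
  res <- lapply(seq_along(probs), function(h) {
    pred_cl <- max.col(probs[[h]], ties.method = "first")
    if (types[h] == "normal") {
      pred <- pred_cl
    } else {
      mp <- majority_mapping(max.col(map_cl[[h]], ties.method = "first"),
                             map_truths, k = ncol(probs[[h]]))
      pred <- apply_mapping(mp, pred_cl)
      # images in clusters unseen on the mapping split count as errors
      pred[is.na(pred)] <- 0L
    }
    data.frame(head = h, type = types[h],
               accuracy = accuracy(pred, truths),
               macro_f1 = macro_f1(pred, truths, k_gt))
  })
  heads <- do.call(rbind, res)
  heads$val_score <- if (is.null(val_scores)) NA_real_ else val_scores
  sel <- if (!is.null(val_scores)) select_best_head(val_scores)
    else select_best_head(heads$macro_f1)
  structure(list(heads = heads, best = sel, split = split,
                 classes = dataset$classes),
            class = "foc_metrics")
}

#' @export
print.foc_metrics <- function(x, ...) {
  cat(sprintf("<foc_metrics> split=%s\n", x$split))
  agg <- stats::aggregate(cbind(accuracy, macro_f1) ~ type, x$heads, max)
  print(agg, row.names = FALSE)
  b <- x$heads[x$best, ]
  cat(sprintf("best head (by validation): #%d (%s), macro-F1 %.4f\n",
              b$head, b$type, b$macro_f1))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics A `foc_metrics` object (or a list of them, e.g. one
#'   per split).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  to_list <- function(m) list(
    split = m$split,
    heads = m$heads,
    best_head = m$heads$head[m$best],
    best_macro_f1 = m$heads$macro_f1[m$best])
  out <- if (inherits(metrics, "foc_metrics")) to_list(metrics)
    else lapply(metrics, to_list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write per-head predictions as CSV
#'
#' One row per image and head: filename, head id, head type, predicted
#' cluster/class id, and the per-output probabilities.
#'
#' @param model A `foc_model` (or `foc_fit`, using its best model).
#' @param dataset A `focr_dataset`.
#' @param path Output CSV path.
#' @param rows Manifest rows to predict (default: all).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(model, dataset, path,
                              rows = seq_len(nrow(dataset$manifest))) {
  if (inherits(model, "foc_fit")) model <- model$best_model
  probs <- predict_heads(model, dataset, rows)
  types <- attr(probs, "types")
  out <- do.call(rbind, lapply(seq_along(probs), function(h) {
    p <- probs[[h]]
    colnames(p) <- paste0("p", seq_len(ncol(p)))
    base <- data.frame(filename = dataset$manifest$filename[rows],
                       head = h, type = types[h],
                       prediction = max.col(p, ties.method = "first"))
    k_all <- max(vapply(probs, ncol, 0L))
    if (ncol(p) < k_all)
      p <- cbind(p, matrix(NA_real_, nrow(p), k_all - ncol(p),
                           dimnames = list(NULL, paste0(
                             "p", (ncol(p) + 1L):k_all))))
    cbind(base, p)
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Consistency score from a judgment CSV
#'
#' Reads expert judgments — columns `filename`, `cluster`, `consistent`
#' and optionally `class` — and computes the [consistency()] report.
#'
#' @param path CSV path.
#' @param exclude_class Optional class to drop (requires a `class`
#'   column).
#' @return A `consistency_report`.
#' @export
consistency_from_csv <- function(path, exclude_class = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster", "consistent")
  if (!all(need %in% names(d)))
    stop("judgment CSV needs columns `cluster` and `consistent`")
  consistency(d$cluster, as.logical(d$consistent),
              classes = d$class, exclude_class = exclude_class)
}
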