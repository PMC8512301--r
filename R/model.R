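#' @title Network with normal and overclustering heads
#'
#' @description
#' The network is a pluggable image backbone followed by several
#' independent linear softmax heads of two kinds: *normal* heads with
#' one output per ground-truth class and *overclustering* heads with
#' more outputs than classes. Heads share the backbone features but are
#' independently initialized.
#'
#' @name model
NULL

#' Backbone specification
#'
#' The default backbone is a small 4-conv-layer CNN sized for CPU
#' training; it is the pluggable component that a residual network
#' would replace at full scale.
#'
#' @param name Architecture name (currently `"tinycnn"`).
#' @param input_size Side length of the network input in pixels
#'   (divisible by 8).
#' @param channels Integer vector of the four conv layer widths.
#' @param input Either `"rgb"` (3 channels) or `"sobel"` (2-channel
#'   gradient transform, see [sobel_transform()]), the usual choice when
#'   no pretrained weights are available.
#' @param pooling Spatial downsampling between conv layers: `"max"`
#'   (default; preserves thin edges) or `"avg"`.
#' @param final How the last conv map becomes the feature vector:
#'   `"flatten"` (default; keeps the coarse spatial layout) or `"gap"`
#'   (global average pooling).
#' @param pretrained Optional path to a checkpoint whose backbone
#'   weights are copied in; never downloaded implicitly.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(name = "tinycnn", input_size = 16L,
                          channels = c(8L, 16L, 24L, 32L),
                          input = c("rgb", "sobel"),
                          pooling = c("max", "avg"),
                          final = c("flatten", "gap"), pretrained = NULL) {
  input <- match.arg(input)
  pooling <- match.arg(pooling)
  final <- match.arg(final)
  structure(list(name = name, input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 in_channels = if (input == "sobel") 2L else 3L,
                 input = input, pooling = pooling, final = final,
                 pretrained = pretrained),
            class = "backbone_spec")
}

#' Head configuration
#'
#' @param type `"normal"` (k_GT outputs) or `"overclustering"`
#'   (`k > k_GT` outputs).
#' @param k Number of outputs of each head copy.
#' @param copies Number of independently initialized copies (default 5).
#' @return A `head_config` list.
#' @export
head_config <- function(type = c("normal", "overclustering"), k,
                        copies = 5L) {
  type <- match.arg(type)
  if (copies < 1L) stop("`copies` must be >= 1")
  structure(list(type = type, k = as.integer(k),
                 copies = as.integer(copies)),
            class = "head_config")
}

#' Build the model
#'
#' Assembles the backbone and all head copies. Every head is a single
#' fully connected layer with softmax activation; overclustering heads
#' must have strictly more outputs than there are ground-truth classes.
#'
#' @param backbone A [backbone_spec()].
#' @param heads List of [head_config()]s.
#' @param k_gt Number of ground-truth classes.
#' @param seed Integer seed for weight initialization.
#' @return A `foc_model`.
#' @examples
#' m <- build_model(backbone_spec(), list(head_config("normal", 6),
#'   head_config("overclustering", 30)), k_gt = 6, seed = 1)
#' @export
build_model <- function(backbone, heads, k_gt, seed = 1L) {
  stopifnot(inherits(backbone, "backbone_spec"))
  for (h in heads) {
    stopifnot(inherits(h, "head_config"))
    if (h$type == "normal" && h$k != k_gt)
      stop("normal heads must have k_gt = ", k_gt, " outputs")
    if (h$type == "overclustering" && h$k <= k_gt)
      stop("overclustering heads need k > k_gt")
  }
  set.seed(as.integer(seed))
  bb <- init_backbone(backbone)
  if (!is.null(backbone$pretrained)) {
    ck <- readRDS(backbone$pretrained)
    bb$params <- ck$model$backbone$params
  }
  n_feat <- if (identical(backbone$final, "gap")) backbone$channels[4]
    else backbone$channels[4] * (backbone$input_size %/% 8L)^2
  head_list <- list()
  for (h in heads)
    for (i in seq_len(h$copies))
      head_list[[length(head_list) + 1L]] <-
        c(init_head(n_feat, h$k), list(type = h$type))
  structure(list(backbone = bb, heads = head_list, k_gt = as.integer(k_gt),
                 seed = as.integer(seed)),
            class = "foc_model")
}

#' @export
print.foc_model <- function(x, ...) {
  types <- vapply(x$heads, `[[`, "", "type")
  ks <- vapply(x$heads, function(h) ncol(h$W), 0L)
  cat(sprintf("<foc_model> %s backbone (%d px, %s channels), %d classes\n",
              x$backbone$spec$name, x$backbone$spec$input_size,
              paste(x$backbone$spec$channels, collapse = "-"), x$k_gt))
  cat(sprintf("  heads: %d normal (k=%d), %d overclustering (k=%d)\n",
              sum(types == "normal"), ks[match("normal", types)],
              sum(types == "overclustering"),
              ks[match("overclustering", types)]))
  invisible(x)
}

# stack a list of H x W x C arrays into the flat batch layout
stack_images <- function(imgs, in_channels = 3L) {
  n <- length(imgs)
  d <- dim(imgs[[1]])
  hw <- d[1] * d[2]
  X <- matrix(0, n * hw, in_channels)
  for (i in seq_len(n))
    X[((i - 1L) * hw + 1L):(i * hw), ] <- matrix(imgs[[i]], hw, in_channels)
  X
}

#' Forward pass
#'
#' Runs images through the backbone and all heads. Inference is
#' deterministic given fixed weights.
#'
#' @param model A `foc_model`.
#' @param images List of image arrays (side length must equal the
#'   backbone `input_size`, channels matching its input mode).
#' @return List with `features` (matrix) and `heads` (list of softmax
#'   probability matrices, one row per image).
#' @export
model_forward <- function(model, images) {
  if (model$backbone$spec$input == "sobel")
    images <- lapply(images, sobel_transform)
  X <- stack_images(images, model$backbone$spec$in_channels)
  fwd <- backbone_forward(model$backbone, X, length(images),
                          keep_cache = FALSE)
  probs <- lapply(model$heads, head_forward, feats = fwd$features)
  list(features = fwd$features, heads = probs)
}

#' Head predictions over a dataset split
#'
#' @param model A `foc_model`.
#' @param dataset A `focr_dataset`.
#' @param rows Manifest rows to predict (default: all).
#' @param batch Images per forward pass.
#' @return List of probability matrices, one per head, with head types
#'   in `attr(, "types")`.
#' @export
predict_heads <- function(model, dataset,
                          rows = seq_len(nrow(dataset$manifest)),
                          batch = 512L) {
  size <- model$backbone$spec$input_size
  out <- NULL
  for (start in seq(1L, length(rows), by = batch)) {
    idx <- rows[start:min(start + batch - 1L, length(rows))]
    imgs <- dataset_images(dataset, idx, size = size)
    p <- model_forward(model, imgs)$heads
    out <- if (is.null(out)) p else Map(rbind, out, p)
  }
  attr(out, "types") <- vapply(model$heads, `[[`, "", "type")
  out
}

#' Select the best head by validation score
#'
#' @param scores Numeric vector of per-head validation scores.
#' @return Index of the maximum; ties broken by the lowest index.
#' @export
select_best_head <- function(scores) {
  if (length(scores) == 0L) stop("empty score list")
  which.max(scores)
}

#' Sobel gradient transform
#'
#' Fixed 2-channel preprocessing used instead of RGB input when no
#' pretrained weights are available: horizontal and vertical gradient
#' magnitudes of the luminance image, computed with the classic 3x3
#' Sobel kernels `Gx = [[-1,0,1],[-2,0,2],[-1,0,1]]` and `Gy = t(Gx)`
#' (zero padding at the borders), each scaled by 1/8.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @return `H x W x 2` array of gradient responses.
#' @export
sobel_transform <- function(img) {
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  h <- nrow(g); w <- ncol(g)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- g
  sh <- function(di, dj) pad[di + (1:h) + 1, dj + (1:w) + 1]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(0, -1) - sh(1, -1)) / 8
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1) -
         sh(-1, -1) - 2 * sh(-1, 0) - sh(-1, 1)) / 8
  array(c(gx, gy), c(h, w, 2))
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the backbone, all heads, the configuration used
#' and the RNG state, so training can be resumed reproducibly.
#'
#' @param model A `foc_model` (or `foc_fit`).
#' @param path File path.
#' @param config Optional training configuration to store alongside.
#' @return `path` invisibly; `load_checkpoint()` returns the stored
#'   list.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  saveRDS(list(model = model, config = config,
               rng = .GlobalEnv$.Random.seed,
               version = as.character(utils::packageVersion("focr"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
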