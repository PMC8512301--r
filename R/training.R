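#' @title Training orchestration
#'
#' @description
#' Full training runs in three phases: an unsupervised *warm-up*
#' (mutual-information loss only, `lambda_s = 0`, no supervised
#' augmentations — the classic invariant-clustering pretext task), a
#' *heads-only* fine-tuning phase with the backbone frozen at a higher
#' learning rate, and the *main* phase training all parameters. Within
#' every phase, epochs alternate between training the normal heads and
#' the overclustering heads. The `foc-light` variant drops the
#' mutual-information loss, the warm-up and the image repetitions, and
#' trains with the supervised losses only.
#'
#' @name training
NULL

#' Training configuration
#'
#' Builds a complete training configuration from a preset plus
#' overrides. The `desk` preset is sized for CPU runs (16 px inputs,
#' small 4-layer backbone, short schedule); the `paper` preset mirrors
#' the full-scale schedule (500 warm-up + 500 main epochs, 100
#' heads-only epochs, learning rates 1e-4/1e-3).
#'
#' Variant constraints are enforced: `foc-light` forces `lambda_u = 0`,
#' no warm-up and no repetitions; `warmup-only` forces `lambda_s = 0`
#' and skips the fine-tuning phases.
#'
#' @param variant `"foc"`, `"foc-light"` or `"warmup-only"`.
#' @param preset `"desk"` or `"paper"`, or a path to a YAML file with
#'   the same fields.
#' @param ... Field overrides (see the preset YAML files under
#'   `inst/config/` for the full list).
#' @param seed Integer seed controlling initialization, batch assembly
#'   and augmentation.
#' @return A `foc_config` list.
#' @examples
#' cfg <- foc_config("foc-light", preset = "desk", seed = 7)
#' cfg$lambda_u    # 0
#' @export
foc_config <- function(variant = c("foc", "foc-light", "warmup-only"),
                       preset = "desk", ..., seed = 1L) {
  variant <- match.arg(variant)
  path <- if (file.exists(preset)) preset else
    system.file("config", paste0(preset, ".yaml"), package = "focr")
  if (path == "") stop("unknown preset: ", preset)
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$variant <- variant
  cfg$seed <- as.integer(seed)
  if (variant == "foc-light") {
    cfg$lambda_u <- 0
    cfg$warmup_epochs <- 0L
    cfg$repetitions <- 1L
    # the light variant exists to cut compute; presets may give it a
    # shorter main schedule (it converges in far fewer epochs without
    # the mutual-information loss and repetitions)
    if (!is.null(cfg$light_main_epochs) && !("main_epochs" %in% names(dots)))
      cfg$main_epochs <- cfg$light_main_epochs
    # with lambda_u = 0 unlabeled samples contribute no gradient at
    # all, so excluding them from batches changes nothing but runtime
    cfg$ratio <- 0
  } else if (variant == "warmup-only") {
    cfg$lambda_s <- 0
    cfg$heads_only_epochs <- 0L
    cfg$main_epochs <- 0L
  }
  if (cfg$lambda_s < 0 || cfg$lambda_u < 0) stop("loss weights must be >= 0")
  structure(cfg, class = "foc_config")
}

#' @export
print.foc_config <- function(x, ...) {
  cat(sprintf(
    "<foc_config> variant=%s lambda_s=%g lambda_u=%g r=%g\n",
    x$variant, x$lambda_s, x$lambda_u, x$ratio))
  cat(sprintf("  epochs: %d warm-up, %d heads-only, %d main; batch %d x%d reps\n",
              x$warmup_epochs, x$heads_only_epochs, x$main_epochs,
              x$batch_size, x$repetitions))
  invisible(x)
}

# pools: which manifest rows act as labeled / unlabeled training data
training_pools <- function(manifest) {
  lab <- which(manifest$split == "train" & !is.na(manifest$hard_label))
  unl <- which((manifest$split == "train" & is.na(manifest$hard_label)) |
                 manifest$split == "unlabeled")
  val <- which(manifest$split == "validation" & !is.na(manifest$hard_label))
  list(labeled = lab, unlabeled = unl, validation = val)
}

# loss and exact gradients for one batch of augmented triplets; pure
# function of the model parameters (given fixed image instances)
batch_loss_grads <- function(model, plan, images, head_idx, weights,
                             eps = 1e-6, policy = "default",
                             need_backbone_grads = TRUE) {
  n <- nrow(plan)
  sup <- which(plan$supervised)
  has_sup <- weights$lambda_s > 0 && length(sup) > 0L
  # the inverse example x3 only enters the supervised loss of
  # overclustering heads; skip its forward pass otherwise
  types <- vapply(model$heads[head_idx], `[[`, "", "type")
  use_x3 <- has_sup && any(types == "overclustering")
  s <- if (use_x3) length(sup) else 0L
  # `policy` may be a single name or a per-manifest-row vector (the
  # auto policy assigns jitter strength per source image)
  srcs <- c(plan$src1, plan$src2, if (s) plan$src3[sup])
  pols <- if (length(policy) > 1L) policy[srcs]
    else rep(policy, length(srcs))
  X <- if (all(pols %in% c("default", "mild"))) {
    augment_stack(images, srcs, pols)
  } else {
    stack_images(Map(function(i, p) augment(images[[i]], p), srcs, pols),
                 dim(images[[srcs[1]]])[3])
  }
  fwd <- backbone_forward(model$backbone, X, 2L * n + s)
  feats <- fwd$features
  n_heads <- length(head_idx)
  dF <- matrix(0, nrow(feats), ncol(feats))
  loss_s <- loss_u <- 0
  head_grads <- list()
  for (h in head_idx) {
    head <- model$heads[[h]]
    q <- head_forward(head, feats)
    k <- ncol(q)
    q1 <- q[seq_len(n), , drop = FALSE]
    q2 <- q[n + seq_len(n), , drop = FALSE]
    dq1 <- matrix(0, n, k)
    dq2 <- matrix(0, n, k)
    dq3 <- NULL
    dlog_ce <- NULL
    Ls <- 0
    if (has_sup) {
      ns <- length(sup)
      y <- plan$y[sup]
      if (head$type == "normal") {
        # Ls = mean over supervised triplets of
        #      0.5*CE(q1, y) + 0.5*CE(q2, y).
        # The gradient is taken directly at the logits (q - onehot),
        # the standard softmax/CE form: it stays informative even when
        # a head is confidently wrong (q[y] below the log clamp).
        r1 <- q1[cbind(sup, y)]
        r2 <- q2[cbind(sup, y)]
        Ls <- mean(-0.5 * log(pmax(r1, eps)) - 0.5 * log(pmax(r2, eps)))
        Y <- matrix(0, ns, k)
        Y[cbind(seq_len(ns), y)] <- 1
        dlog_ce <- matrix(0, nrow(q), k)
        dlog_ce[sup, ] <- 0.5 * (q1[sup, , drop = FALSE] - Y) / ns
        dlog_ce[n + sup, ] <- 0.5 * (q2[sup, , drop = FALSE] - Y) / ns
      } else {
        # Ls = mean of 0.5*CEinv(q1, q3) + 0.5*CEinv(q2, q3); the
        # reciprocal is clamped but not masked, so the pulled-back
        # logit gradient stays bounded and non-zero at saturation
        q3 <- q[2L * n + seq_len(s), , drop = FALSE]
        q1s <- q1[sup, , drop = FALSE]
        q2s <- q2[sup, , drop = FALSE]
        om <- pmax(1 - q3, eps)
        lom <- log(om)
        Ls <- mean(-0.5 * rowSums((q1s + q2s) * lom))
        dq1[sup, ] <- -0.5 * lom / s
        dq2[sup, ] <- -0.5 * lom / s
        dq3 <- 0.5 * (q1s + q2s) / om / s
      }
    }
    Lu <- 0
    if (weights$lambda_u > 0) {
      J <- joint_distribution(q1, q2)
      Lu <- -mutual_information(J, eps)
      pr <- rowSums(J)
      pc <- colSums(J)
      # d I / d P = log(P / (pr x pc)) - 1 away from the clamps
      G <- log(pmax(J, eps)) - log(pmax(outer(pr, pc), eps)) - 1
      dq1 <- dq1 * weights$lambda_s - weights$lambda_u * (q2 %*% G) / n
      dq2 <- dq2 * weights$lambda_s - weights$lambda_u * (q1 %*% G) / n
    } else {
      dq1 <- dq1 * weights$lambda_s
      dq2 <- dq2 * weights$lambda_s
    }
    dq <- rbind(dq1, dq2,
                if (s) weights$lambda_s * dq3)
    dlog <- softmax_backward(q, dq)
    if (!is.null(dlog_ce)) dlog <- dlog + weights$lambda_s * dlog_ce
    dlog <- dlog / n_heads
    head_grads[[as.character(h)]] <-
      list(W = crossprod(feats, dlog), b = colSums(dlog))
    dF <- dF + dlog %*% t(head$W)
    loss_s <- loss_s + Ls / n_heads
    loss_u <- loss_u + Lu / n_heads
  }
  loss <- weights$lambda_s * loss_s + weights$lambda_u * loss_u
  if (!is.finite(loss))
    stop(sprintf("non-finite loss (Ls=%g, Lu=%g); aborting", loss_s, loss_u))
  backbone_grads <- if (need_backbone_grads)
    backbone_backward(model$backbone, fwd$cache, dF)
  list(loss = loss, loss_s = loss_s, loss_u = loss_u,
       head_grads = head_grads, backbone_grads = backbone_grads)
}

# one optimization step on one batch; returns model, states and losses
train_batch <- function(model, plan, images, head_idx, weights, lr,
                        opt, policy, eps = 1e-6, freeze_backbone = FALSE) {
  g <- batch_loss_grads(model, plan, images, head_idx, weights, eps,
                        policy, need_backbone_grads = !freeze_backbone)
  for (h in head_idx) {
    st <- adam_step(model$heads[[h]][c("W", "b")],
                    g$head_grads[[as.character(h)]], opt$heads[[h]], lr)
    model$heads[[h]][c("W", "b")] <- st$params
    opt$heads[[h]] <- st$state
  }
  if (!freeze_backbone) {
    st <- adam_step(model$backbone$params, g$backbone_grads,
                    opt$backbone, lr)
    model$backbone$params <- st$params
    opt$backbone <- st$state
  }
  list(model = model, opt = opt, loss = g$loss, loss_s = g$loss_s,
       loss_u = g$loss_u)
}

#' Train one epoch
#'
#' Low-level epoch driver: applies the combined loss to every batch and
#' takes Adam steps on the backbone (unless frozen) and on the heads of
#' the requested type. The supervised loss is cross-entropy for normal
#' heads and inverse cross-entropy for overclustering heads; the
#' unsupervised loss is the negated mutual information of the two
#' augmented views; per-head losses are averaged across the head
#' copies.
#'
#' @param model A `foc_model`.
#' @param batches Batch plans from [assemble_batches()].
#' @param images List of pre-rendered image arrays, indexable by the
#'   plan's source columns.
#' @param head_type `"normal"` or `"overclustering"`.
#' @param weights A [loss_weights()].
#' @param lr Learning rate.
#' @param opt Optimizer state from a previous call, or `NULL`.
#' @param policy Augmentation policy name.
#' @param freeze_backbone Keep backbone parameters fixed.
#' @param eps Numerical clamp inside all logarithms.
#' @return List with the updated `model`, `opt` state and the mean
#'   `loss`, `loss_s`, `loss_u` over the epoch.
#' @export
train_epoch <- function(model, batches, images, head_type, weights,
                        lr, opt = NULL, policy = "default",
                        freeze_backbone = FALSE, eps = 1e-6) {
  head_idx <- which(vapply(model$heads, `[[`, "", "type") == head_type)
  if (!length(head_idx)) stop("model has no ", head_type, " heads")
  if (is.null(opt))
    opt <- list(backbone = adam_init(model$backbone$params),
                heads = lapply(model$heads, function(h)
                  adam_init(h[c("W", "b")])))
  tot <- c(loss = 0, loss_s = 0, loss_u = 0)
  for (b in batches) {
    res <- train_batch(model, b, images, head_idx, weights, lr, opt,
                       policy, eps, freeze_backbone)
    model <- res$model
    opt <- res$opt
    tot <- tot + c(res$loss, res$loss_s, res$loss_u)
  }
  tot <- tot / max(1L, length(batches))
  list(model = model, opt = opt, loss = tot[["loss"]],
       loss_s = tot[["loss_s"]], loss_u = tot[["loss_u"]])
}

# per-head validation macro-F1 (overclustering heads are mapped by
# majority vote on the same rows); `X` is the pre-stacked flat batch
validation_scores <- function(model, X, n, truths, k_gt) {
  feats <- backbone_forward(model$backbone, X, n, keep_cache = FALSE)$features
  probs <- lapply(model$heads, head_forward, feats = feats)
  vapply(seq_along(probs), function(h) {
    pred_cl <- max.col(probs[[h]], ties.method = "first")
    if (model$heads[[h]]$type == "normal") {
      macro_f1(pred_cl, truths, k_gt)
    } else {
      mp <- majority_mapping(pred_cl, truths, k = ncol(probs[[h]]))
      macro_f1(apply_mapping(mp, pred_cl), truths, k_gt)
    }
  }, numeric(1))
}

#' Train the full framework
#'
#' Runs the phase schedule of the selected variant on a dataset:
#' warm-up (if any), heads-only fine-tuning with frozen backbone, and
#' the main phase, alternating the trained head type every epoch.
#' Validation macro-F1 is computed per head after every fine-tuning
#' epoch and the best-scoring model state is retained for evaluation.
#'
#' Labeled training data are the train-split rows with a hard label;
#' train-split rows without one and the whole unlabeled split form the
#' unlabeled pool.
#'
#' @param dataset A `focr_dataset`.
#' @param config A [foc_config()].
#' @param model Optional `foc_model` to continue training (e.g. the
#'   result of a [warmup()]); by default a fresh model is initialized.
#' @return A `foc_fit`: list with `model` (final), `best_model` (best
#'   validation state), `val_scores` (per head, at the best epoch),
#'   `log` (per-epoch data.frame), `config`, and `classes`.
#' @export
train_foc <- function(dataset, config, model = NULL) {
  stopifnot(inherits(config, "foc_config"))
  man <- dataset$manifest
  k_gt <- length(dataset$classes)
  pools <- training_pools(man)
  if (!length(pools$labeled)) stop("dataset has no labeled training rows")
  labels <- man$hard_label[pools$labeled]

  bspec <- backbone_spec(input_size = config$input_size,
                         channels = config$channels,
                         input = config$input,
                         pretrained = config$pretrained)
  k_over <- if (is.null(config$k_over)) 5L * k_gt else config$k_over
  if (is.null(model))
    model <- build_model(bspec,
                         list(head_config("normal", k_gt, config$head_copies),
                              head_config("overclustering", k_over,
                                          config$head_copies)),
                         k_gt, seed = mix_seed(config$seed, 5L))

  need <- sort(unique(c(pools$labeled, pools$unlabeled, pools$validation)))
  images <- vector("list", nrow(man))
  images[need] <- dataset_images(dataset, need, size = config$input_size)
  if (bspec$input == "sobel") images[need] <- lapply(images[need],
                                                     sobel_transform)
  val_rows <- pools$validation
  if (!is.null(config$val_max) && length(val_rows) > config$val_max) {
    set.seed(mix_seed(config$seed, 7L))
    val_rows <- sort(sample(val_rows, config$val_max))
  }
  val_truths <- man$hard_label[val_rows]
  val_X <- if (length(val_rows))
    stack_images(images[val_rows], bspec$in_channels)

  # "auto" augmentation: strong hue/aspect jitter is label-preserving
  # for certain anchor images (their class sits far from any boundary)
  # but not for ambiguous images carrying a most-likely-class label, so
  # jitter strength is assigned per source image from its certainty
  policy <- config$augmentation
  if (identical(policy, "auto")) {
    policy <- if (all(man$certain)) "default" else
      ifelse(man$certain, "default", "mild")
  }

  bs <- batch_spec(config$batch_size, config$ratio, config$repetitions)
  bs_warm <- batch_spec(config$batch_size, config$ratio,
                        max(config$repetitions, 1L))
  opt <- NULL
  log <- list()
  best <- list(score = -Inf, model = NULL, scores = NULL)
  epoch <- 0L
  phases <- list(
    list(name = "warmup", epochs = config$warmup_epochs,
         lr = config$lr_warmup, freeze = FALSE,
         weights = loss_weights(0, config$lambda_u)),
    list(name = "heads_only", epochs = config$heads_only_epochs,
         lr = config$lr_heads_only, freeze = TRUE,
         weights = loss_weights(config$lambda_s, config$lambda_u)),
    list(name = "main", epochs = config$main_epochs,
         lr = config$lr_main, freeze = FALSE,
         weights = loss_weights(config$lambda_s, config$lambda_u)))
  for (ph in phases) {
    if (ph$epochs <= 0L) next
    for (e in seq_len(ph$epochs)) {
      epoch <- epoch + 1L
      head_type <- if (epoch %% 2L == 1L) "normal" else "overclustering"
      warmup_mode <- ph$name == "warmup"
      # anneal the last quarter of the main phase for fine convergence
      lr_e <- ph$lr
      if (ph$name == "main" && !is.null(config$lr_decay) &&
          e > 0.75 * ph$epochs)
        lr_e <- ph$lr * config$lr_decay
      # warm-up ignores labels entirely: no supervised augmentation,
      # no inverse examples
      plan_labels <- if (warmup_mode) rep(NA_integer_, length(labels))
        else labels
      batches <- assemble_batches(
        pools$labeled, pools$unlabeled, plan_labels,
        if (warmup_mode) bs_warm else bs,
        seed = config$seed, epoch = epoch,
        n_batches = config$batches_per_epoch)
      set.seed(mix_seed(config$seed, 11L, epoch))
      res <- train_epoch(model, batches, images, head_type, ph$weights,
                         lr_e, opt, policy = policy,
                         freeze_backbone = ph$freeze, eps = config$eps)
      model <- res$model
      opt <- res$opt
      vs <- NULL
      eval_every <- if (is.null(config$eval_every)) 1L else config$eval_every
      is_last <- ph$name == "main" && e == ph$epochs
      if (!warmup_mode && length(val_rows) &&
          (epoch %% eval_every == 0L || is_last)) {
        vs <- validation_scores(model, val_X, length(val_rows),
                                val_truths, k_gt)
        # checkpoints within the sampling noise of the validation score
        # count as ties, and ties resolve to the most recent state:
        # when validation saturates, the longer-trained model is the
        # better calibrated one
        if (max(vs) >= best$score - 0.005) {
          best <- list(score = max(max(vs), best$score), model = model,
                       scores = vs)
        }
      }
      log[[epoch]] <- data.frame(
        phase = ph$name, epoch = epoch, head_type = head_type,
        lr = lr_e, loss = res$loss, loss_s = res$loss_s,
        loss_u = res$loss_u,
        val_best = if (is.null(vs)) NA_real_ else max(vs))
    }
  }
  if (is.null(best$model)) best <- list(score = NA_real_, model = model,
                                        scores = NULL)
  structure(list(model = model, best_model = best$model,
                 val_scores = best$scores, log = do.call(rbind, log),
                 config = config, classes = dataset$classes),
            class = "foc_fit")
}

#' @export
print.foc_fit <- function(x, ...) {
  cat(sprintf("<foc_fit> variant=%s, %d epochs trained\n",
              x$config$variant, nrow(x$log)))
  if (!is.null(x$val_scores))
    cat(sprintf("  best validation macro-F1: %.3f (head %d)\n",
                max(x$val_scores), select_best_head(x$val_scores)))
  invisible(x)
}

#' Unsupervised warm-up
#'
#' Convenience wrapper running only the warm-up phase (`lambda_s = 0`,
#' mutual-information loss only, no supervised augmentations) of a
#' configuration. Equivalent to [train_foc()] with the fine-tuning
#' phases disabled.
#'
#' @inheritParams train_foc
#' @return A `foc_fit`.
#' @export
warmup <- function(dataset, config) {
  if (config$variant == "foc-light")
    stop("the foc-light variant has no warm-up phase")
  config$lambda_s <- 0
  config$heads_only_epochs <- 0L
  config$main_epochs <- 0L
  train_foc(dataset, config)
}

#' Fine-tuning phases
#'
#' Convenience wrapper running the heads-only and main phases of a
#' configuration on an already-initialized model (e.g. after a
#' warm-up), i.e. [train_foc()] with `warmup_epochs = 0` starting from
#' `model`.
#'
#' @inheritParams train_foc
#' @return A `foc_fit`.
#' @export
finetune <- function(dataset, config, model = NULL) {
  config$warmup_epochs <- 0L
  train_foc(dataset, config, model = model)
}
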