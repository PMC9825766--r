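# Training regimes: per-tissue Base training, multi-task learning with a
# pretrained (frozen) shared extractor plus a tissue-specific private
# extractor, and transfer learning (pretrain on pooled source tissues,
# fine-tune everything on the target tissue).

#' Training configuration
#'
#' Binary cross-entropy loss optimized with Adam. The learning rate starts
#' at `lr` and decays exponentially by `decay` per epoch. Training stops at
#' `max_epochs` or when the validation loss has not decreased for `patience`
#' consecutive epochs, whichever comes first; the weights with the best
#' observed validation loss are restored.
#'
#' @param lr Initial learning rate (default 1e-4).
#' @param decay Per-epoch exponential decay factor (default 0.96).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(lr = 1e-4, decay = 0.96, max_epochs = 200L,
                         patience = 5L, batch_size = 64L, seed = 1L,
                         verbose = FALSE) {
  if (patience < 1) stopf("`patience` must be >= 1")
  if (max_epochs < patience) stopf("`max_epochs` must be >= `patience`")
  structure(list(lr = lr, decay = decay, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

eval_loss <- function(model, bundles, idx, extra = NULL, batch_size = 512L) {
  losses <- numeric(0); ws <- numeric(0)
  for (ix in split(idx, ceiling(seq_along(idx) / batch_size))) {
    bb <- subset_bundles(bundles, ix)
    ex <- if (!is.null(extra)) extra[ix, , drop = FALSE] else NULL
    p <- model_forward(model, bb, train = FALSE, extra = ex)$p
    losses <- c(losses, bce_loss(p, bb$label))
    ws <- c(ws, length(ix))
  }
  sum(losses * ws) / sum(ws)
}

# Core mini-batch training loop shared by all paradigms. `extra` is an
# optional n x k matrix of fixed precomputed features (frozen shared
# extractor output) appended to the classifier input.
fit_network <- function(model, bundles, train_idx, val_idx, tcfg,
                        extra = NULL) {
  if (length(train_idx) == 0 || length(val_idx) == 0) {
    stopf("empty training or validation split")
  }
  with_seed_(tcfg$seed, {
    params <- collect_params(model)
    if (isTRUE(model$frozen)) {
      params <- params[grep("^clf\\.", names(params))]
    }
    opt <- adam_init(params)
    best <- Inf
    best_params <- params
    best_bn <- collect_bn_state(model)
    bad <- 0L
    history <- data.frame(epoch = integer(0), lr = numeric(0),
                          train_loss = numeric(0), val_loss = numeric(0))
    for (epoch in seq_len(tcfg$max_epochs)) {
      lr <- tcfg$lr * tcfg$decay^(epoch - 1)
      ord <- sample(train_idx)
      batch_losses <- numeric(0)
      for (bx in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
        bb <- subset_bundles(bundles, bx)
        ex <- if (!is.null(extra)) extra[bx, , drop = FALSE] else NULL
        fw <- model_forward(model, bb, train = TRUE, extra = ex)
        model <- fw$model  # batch-norm running stats advanced
        y <- bb$label
        batch_losses <- c(batch_losses, bce_loss(fw$p, y))
        dlogits <- (fw$p - y) / length(y)
        grads <- collect_grads(model, model_backward(model, fw$cache, dlogits))
        st <- adam_step(params, grads, opt, lr)
        params <- st$params
        opt <- st$state
        model <- assign_params(model, params)
      }
      val_loss <- eval_loss(model, bundles, val_idx, extra)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr,
        train_loss = mean(batch_losses), val_loss = val_loss))
      if (tcfg$verbose) {
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, mean(batch_losses), val_loss))
      }
      if (val_loss < best) {
        best <- val_loss
        best_params <- params
        best_bn <- collect_bn_state(model)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= tcfg$patience) break
      }
    }
    model <- assign_params(model, best_params)
    if (length(best_bn) > 0) model <- assign_bn_state(model, best_bn)
    list(model = model, history = history, best_val_loss = best)
  })
}

#' Train the base (single-tissue) classifier
#'
#' @param bundles `"feature_bundles"` for the target tissue.
#' @param split A `"dataset_split"` with `train` and `validation` indices.
#' @param model_cfg A [model_config()]; its `seed` controls initialization.
#' @param train_cfg A [train_config()].
#' @return A list of class `"trained_network"`: `model`, per-epoch `history`
#'   and `best_val_loss`.
#' @export
train_base <- function(bundles, split, model_cfg, train_cfg = train_config()) {
  model <- build_model(model_cfg)
  fit <- fit_network(model, bundles, split$train, split$validation, train_cfg)
  structure(c(fit, list(paradigm = "base")), class = "trained_network")
}

#' Pretrain a shared feature extractor on pooled source tissues
#'
#' Pools the labeled interactions of all source tissues (the target tissue
#' must not be present), splits 85/15 into training/validation, and trains a
#' full network whose extractor becomes the shared extractor; the
#' classification head is a throwaway.
#'
#' @param bundle_list Named list of `"feature_bundles"`, one per source
#'   tissue.
#' @param exclude Identifier of the target tissue; an error is raised if it
#'   appears among the sources.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param fractions Pretraining split fractions (default `c(0.85, 0.15)`).
#' @param split_seed Seed for the pooled split.
#' @return A `"trained_network"` whose `model` carries the shared extractor.
#' @export
pretrain_shared <- function(bundle_list, exclude, model_cfg,
                            train_cfg = train_config(),
                            fractions = c(0.85, 0.15), split_seed = 1L) {
  if (length(bundle_list) < 1) stopf("need at least one source tissue")
  if (!is.null(exclude) && exclude %in% names(bundle_list)) {
    stopf("configuration error: target tissue '%s' present in the pretraining pool", exclude)
  }
  pooled <- concat_bundles(bundle_list)
  split <- split_dataset(pooled$meta$n, fractions, seed = split_seed)
  model <- build_model(model_cfg)
  fit <- fit_network(model, pooled, split$train, split$validation, train_cfg)
  structure(c(fit, list(paradigm = "pretrain", split = split)),
            class = "trained_network")
}

#' Concatenate feature bundles across tissues
#' @param bundle_list Named list of `"feature_bundles"` with identical
#'   component sets and shapes.
#' @return One pooled `"feature_bundles"` object.
#' @export
concat_bundles <- function(bundle_list) {
  comps <- intersect(c("S", "R", "aux"), names(bundle_list[[1]]))
  out <- list()
  for (cm in comps) {
    arrs <- lapply(bundle_list, `[[`, cm)
    d <- dim(arrs[[1]])
    ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
    big <- array(0, c(sum(ns), d[2], d[3], d[4]))
    off <- 0L
    for (a in arrs) {
      big[(off + 1):(off + dim(a)[1]), , , ] <- a
      off <- off + dim(a)[1]
    }
    out[[cm]] <- big
  }
  if (!is.null(bundle_list[[1]]$D)) out$D <- unlist(lapply(bundle_list, `[[`, "D"), use.names = FALSE)
  out$label <- unlist(lapply(bundle_list, `[[`, "label"), use.names = FALSE)
  out$meta <- list(
    tissue = unlist(lapply(bundle_list, function(b) b$meta$tissue)),
    itype = unique(unlist(lapply(bundle_list, function(b) b$meta$itype))),
    n = length(out$label),
    active = bundle_list[[1]]$meta$active
  )
  structure(out, class = "feature_bundles")
}

#' Train the multi-task (shared/private) classifier for a target tissue
#'
#' The pretrained shared extractor is frozen; its fused features are the
#' common features. A private extractor of identical architecture is trained
#' on the target tissue, and the tissue-specific classifier consumes the
#' concatenation of common and private features (plus distance when active).
#'
#' @param bundles Target-tissue `"feature_bundles"`.
#' @param split Target `"dataset_split"` (train/validation).
#' @param shared A `"trained_network"` from [pretrain_shared()] (or its
#'   `model`).
#' @param model_cfg [model_config()] for the private extractor (must match
#'   the shared extractor's feature geometry).
#' @param train_cfg A [train_config()].
#' @return A `"trained_network"` whose `model` has `mode = "multitask"`.
#' @export
train_multitask <- function(bundles, split, shared, model_cfg,
                            train_cfg = train_config()) {
  smodel <- if (inherits(shared, "trained_network")) shared$model else shared
  if (is.null(smodel$extractor)) stopf("shared model has no feature extractor")
  # frozen shared extractor: its fused features are fixed inputs
  shared_feats <- extract_features(smodel, bundles)
  private <- build_model(model_cfg)
  # widen the classifier input for the prepended common features
  clf_in <- ncol(shared_feats) + private$fused_dim + ("D" %in% model_cfg$active)
  with_seed_(model_cfg$seed, {
    private$classifier$fc1 <- dense_build(clf_in, model_cfg$fc_width, "relu")
    private$classifier$fc2 <- dense_build(model_cfg$fc_width, 1L, "linear")
  })
  fit <- fit_network(private, bundles, split$train, split$validation, train_cfg,
                     extra = shared_feats)
  model <- fit$model
  model$mode <- "multitask"
  model$shared <- list(cfg = smodel$cfg, extractor = smodel$extractor,
                       head = smodel$classifier)
  model$frozen <- TRUE
  fit$model <- model
  structure(c(fit, list(paradigm = "multitask")), class = "trained_network")
}

#' Train the transfer-learning classifier for a target tissue
#'
#' The network is initialized from the pretrained shared extractor (the
#' pretraining head is discarded, a fresh classifier is attached) and all
#' layers are then fine-tuned on the target tissue.
#'
#' @inheritParams train_multitask
#' @return A `"trained_network"` (`mode = "base"` network, fine-tuned).
#' @export
train_transfer <- function(bundles, split, shared, model_cfg,
                           train_cfg = train_config()) {
  smodel <- if (inherits(shared, "trained_network")) shared$model else shared
  if (is.null(smodel$extractor)) stopf("shared model has no feature extractor")
  model <- build_model(model_cfg)
  model$extractor <- smodel$extractor  # initialize from pretrained weights
  fit <- fit_network(model, bundles, split$train, split$validation, train_cfg)
  structure(c(fit, list(paradigm = "transfer")), class = "trained_network")
}

#' Select source tissues for pretraining
#'
#' @param tissues Character vector of all tissue identifiers.
#' @param target Target tissue (always excluded from the result).
#' @param mode `"all_others"`, `"group"` (a predefined biologically relevant
#'   group minus the target) or `"top_k"` (most similar tissues by a
#'   similarity matrix, see [similarity_matrix()]).
#' @param group Character vector naming the predefined group (for
#'   `mode = "group"`).
#' @param sim Similarity matrix (for `mode = "top_k"`).
#' @param k Number of top similar tissues (default 5).
#' @return Character vector of selected source tissues.
#' @export
select_pretraining_tissues <- function(tissues, target,
                                       mode = c("all_others", "group", "top_k"),
                                       group = NULL, sim = NULL, k = 5L) {
  mode <- match.arg(mode)
  if (!target %in% tissues) stopf("unknown target tissue '%s'", target)
  switch(mode,
    all_others = setdiff(tissues, target),
    group = {
      if (is.null(group)) stopf("`group` required for mode = 'group'")
      unknown <- setdiff(group, tissues)
      if (length(unknown) > 0) {
        stopf("unknown group member(s): %s", paste(unknown, collapse = ", "))
      }
      setdiff(group, target)
    },
    top_k = {
      if (is.null(sim)) stopf("`sim` required for mode = 'top_k'")
      top_k_similar(sim, target, k = k)
    }
  )
}
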