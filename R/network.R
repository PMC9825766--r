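# Declarative model configuration and the interaction classifier.
#
# Architecture: each active array modality (S = one-hot sequence, R =
# windowed coverage, aux = windowed conservation/shape) is passed through
# its own dense block of four convolution layers (filters 64/32/16/16,
# dilation rates 1-4, concatenative skip connections). The sequence block's
# entry layer uses kernel 20x4 with stride 10x4; the read/aux blocks use
# kernel 3x1 with stride 1x1. Block outputs are flattened to
# (positions x channels) grids, stacked row-wise, and fused by a
# convolution layer with kernel 4x4 and stride 4x4, followed by global
# average pooling. The pooled fused features are concatenated with the
# scalar anchor distance (D) and classified by a 256-unit ReLU layer with a
# sigmoid output.

#' Model configuration
#'
#' Declarative description of the classifier architecture. The defaults are
#' the full-scale geometry (2 kb anchors, 21 coverage windows, 4 epigenetic
#' tracks); smaller geometries for quick experiments are obtained by
#' overriding `anchor_len`, `n_windows`, `filters` etc.
#'
#' @param active Character subset of `c("S","R","D","aux")`; at least one.
#' @param anchor_len Standardized anchor length in bp (default 2000).
#' @param n_windows Coverage windows per anchor per track (default 21).
#' @param n_tracks Number of epigenetic read tracks M (default 4: open
#'   chromatin, H3K4me3, H3K4me1, H3K27ac).
#' @param n_aux Number of auxiliary (conservation/DNA-shape) tracks.
#' @param seq_kernel,seq_stride Entry kernel/stride of the sequence block
#'   (defaults `c(20,4)` and `c(10,4)`).
#' @param read_kernel,read_stride Entry kernel/stride of the read/aux blocks
#'   (defaults `c(3,1)` and `c(1,1)`).
#' @param filters In-block filter counts (default `c(64,32,16,16)`).
#' @param dilations In-block dilation rates (default `1:4`).
#' @param fusion_kernel,fusion_stride Fusion convolution geometry (defaults
#'   `c(4,4)` / `c(4,4)`).
#' @param fusion_filters Fusion convolution filters (default 64).
#' @param fc_width Classifier hidden width (default 256).
#' @param dropout Dropout rate inside convolution layers (default 0.2).
#' @param prelu_init Initial PReLU slope (default 0.25).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(active = c("S", "R", "D"), anchor_len = 2000L,
                         n_windows = 21L, n_tracks = 4L, n_aux = 0L,
                         seq_kernel = c(20L, 4L), seq_stride = c(10L, 4L),
                         read_kernel = c(3L, 1L), read_stride = c(1L, 1L),
                         filters = c(64L, 32L, 16L, 16L), dilations = 1:4,
                         fusion_kernel = c(4L, 4L), fusion_stride = c(4L, 4L),
                         fusion_filters = 64L, fc_width = 256L,
                         dropout = 0.2, prelu_init = 0.25, seed = NULL) {
  active <- match.arg(active, c("S", "R", "D", "aux"), several.ok = TRUE)
  if (length(active) == 0) stopf("at least one feature must be active")
  if (any(filters <= 0) || fc_width <= 0 || fusion_filters <= 0) {
    stopf("filter counts and widths must be positive")
  }
  if (any(dilations < 1)) stopf("dilation rates must be >= 1")
  structure(list(
    active = active, anchor_len = as.integer(anchor_len),
    n_windows = as.integer(n_windows), n_tracks = as.integer(n_tracks),
    n_aux = as.integer(n_aux),
    seq_kernel = as.integer(seq_kernel), seq_stride = as.integer(seq_stride),
    read_kernel = as.integer(read_kernel), read_stride = as.integer(read_stride),
    filters = as.integer(filters), dilations = as.integer(dilations),
    fusion_kernel = as.integer(fusion_kernel),
    fusion_stride = as.integer(fusion_stride),
    fusion_filters = as.integer(fusion_filters),
    fc_width = as.integer(fc_width), dropout = dropout,
    prelu_init = prelu_init, seed = seed
  ), class = "model_config")
}

array_modalities <- function(cfg) intersect(c("S", "R", "aux"), cfg$active)

modality_input_shape <- function(cfg, mod) {
  switch(mod,
    S = c(cfg$anchor_len, 4L, 2L),
    R = c(cfg$n_windows, cfg$n_tracks, 2L),
    aux = c(cfg$n_windows, cfg$n_aux, 2L)
  )
}

#' Build an untrained interaction classifier
#'
#' Constructs the network described by a [model_config()]: one dense block
#' per active array modality, a fusion convolution over the stacked block
#' outputs, global average pooling, distance concatenation, and the
#' classifier head. With `active = "D"` the model reduces to the classifier
#' on the scalar distance alone (no convolutional path).
#'
#' @param cfg A `"model_config"`.
#' @return An object of class `"phic_model"` (untrained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed_(cfg$seed, {
    mods <- array_modalities(cfg)
    extractor <- NULL
    fused_dim <- 0L
    if (length(mods) > 0) {
      blocks <- list()
      for (mod in mods) {
        sh <- modality_input_shape(cfg, mod)
        if (mod == "S") {
          blocks[[mod]] <- block_build(sh[1], sh[2], sh[3], cfg$seq_kernel,
                                       cfg$seq_stride, cfg$filters,
                                       cfg$dilations, cfg$dropout, cfg$prelu_init)
        } else {
          blocks[[mod]] <- block_build(sh[1], sh[2], sh[3], cfg$read_kernel,
                                       cfg$read_stride, cfg$filters,
                                       cfg$dilations, cfg$dropout, cfg$prelu_init)
        }
      }
      rows <- vapply(blocks, function(b) b$out_shape[1] * b$out_shape[2], numeric(1))
      grid_c <- sum(cfg$filters)
      fusion <- conv_build(as.integer(sum(rows)), grid_c, 1L, cfg$fusion_filters,
                           cfg$fusion_kernel, cfg$fusion_stride, dilation = 1L,
                           pad_h = FALSE, dropout = cfg$dropout,
                           prelu_init = cfg$prelu_init)
      extractor <- list(blocks = blocks, fusion = fusion,
                        rows = as.integer(rows), grid_c = grid_c)
      fused_dim <- cfg$fusion_filters
    }
    clf_in <- fused_dim + ("D" %in% cfg$active)
    classifier <- list(
      fc1 = dense_build(clf_in, cfg$fc_width, "relu"),
      fc2 = dense_build(cfg$fc_width, 1L, "linear")
    )
    structure(list(cfg = cfg, extractor = extractor, classifier = classifier,
                   mode = "base", fused_dim = fused_dim, shared = NULL),
              class = "phic_model")
  })
}

#' Build a feature-ablated variant of the classifier
#'
#' @param cfg A `"model_config"` whose `active` set is replaced.
#' @param active Nonempty subset of `c("S","R","D","aux")`.
#' @return An untrained `"phic_model"` consuming exactly `active`.
#' @export
build_ablation <- function(cfg, active) {
  if (length(active) == 0) stopf("`active` must be a nonempty feature subset")
  cfg$active <- match.arg(active, c("S", "R", "D", "aux"), several.ok = TRUE)
  build_model(cfg)
}

# ---- forward / backward through a full model -------------------------------

extractor_forward <- function(extr, cfg, bundles, train) {
  mods <- array_modalities(cfg)
  N <- NULL
  bouts <- list(); bcaches <- list()
  for (mod in mods) {
    X <- bundles[[mod]]
    if (is.null(X)) stopf("bundle is missing active component '%s'", mod)
    sh <- modality_input_shape(cfg, mod)
    if (!identical(dim(X)[-1], as.integer(sh))) {
      stopf("shape mismatch for '%s': bundle (%s) vs config (%s)", mod,
            paste(dim(X)[-1], collapse = "x"), paste(sh, collapse = "x"))
    }
    N <- dim(X)[1]
    r <- block_forward(extr$blocks[[mod]], X, train)
    bouts[[mod]] <- r$out
    bcaches[[mod]] <- r$caches
    extr$blocks[[mod]] <- r$block
  }
  # stack per-modality (positions x channels) grids row-wise
  G <- array(0, c(N, sum(extr$rows), extr$grid_c, 1L))
  off <- 0L
  for (i in seq_along(mods)) {
    b <- bouts[[mods[i]]]
    d <- dim(b)
    dim(b) <- c(d[1], d[2] * d[3], d[4])
    G[, (off + 1):(off + extr$rows[i]), , 1] <- b
    off <- off + extr$rows[i]
  }
  fr <- conv_forward(extr$fusion, G, train)
  extr$fusion <- fr$layer
  gp <- gap_forward(fr$out)
  list(fused = gp$out, extractor = extr,
       cache = list(bcaches = bcaches, fusion = fr$cache, gap_dims = gp$dims,
                    bdims = lapply(bouts, dim), N = N))
}

extractor_backward <- function(extr, cfg, cache, dfused) {
  mods <- array_modalities(cfg)
  dF <- gap_backward(dfused, cache$gap_dims)
  fr <- conv_backward(extr$fusion, cache$fusion, dF)
  grads <- list(fusion = fr$grads)
  dG <- fr$dX
  off <- 0L
  for (i in seq_along(mods)) {
    mod <- mods[i]
    db <- dG[, (off + 1):(off + extr$rows[i]), , 1, drop = FALSE]
    off <- off + extr$rows[i]
    dim(db) <- cache$bdims[[mod]]
    br <- block_backward(extr$blocks[[mod]], cache$bcaches[[mod]], db)
    grads[[mod]] <- br$grads
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass of the full model. `extra` is an optional matrix of
# precomputed features prepended to the classifier input (used for the
# frozen shared extractor in the multi-task paradigm).
model_forward <- function(model, bundles, train = FALSE, extra = NULL) {
  cfg <- model$cfg
  n <- bundles$meta$n %||% (if (!is.null(bundles$D)) length(bundles$D) else dim(bundles[[array_modalities(cfg)[1]]])[1])
  parts <- list()
  ecache <- NULL
  if (!is.null(model$extractor)) {
    # a frozen extractor runs in inference mode even while the classifier
    # trains: no dropout, no batch-norm statistic drift
    ext_train <- train && !isTRUE(model$frozen)
    er <- extractor_forward(model$extractor, cfg, bundles, ext_train)
    model$extractor <- er$extractor
    ecache <- er$cache
    parts$fused <- er$fused
  }
  if (!is.null(extra)) parts$extra <- extra
  if ("D" %in% cfg$active) {
    if (is.null(bundles$D)) stopf("bundle is missing active component 'D'")
    parts$D <- matrix(bundles$D, ncol = 1)
  }
  clf_in <- do.call(cbind, parts[intersect(c("extra", "fused", "D"), names(parts))])
  f1 <- dense_forward(model$classifier$fc1, clf_in)
  f2 <- dense_forward(model$classifier$fc2, f1$out)
  p <- sigmoid(as.vector(f2$out))
  list(p = p, model = model,
       cache = list(ecache = ecache, f1 = f1$cache, f2 = f2$cache,
                    fused_cols = ncol(parts$fused %||% matrix(nrow = 0, ncol = 0)),
                    extra_cols = if (is.null(extra)) 0L else ncol(extra)))
}

model_backward <- function(model, cache, dlogits) {
  b2 <- dense_backward(model$classifier$fc2, cache$f2, matrix(dlogits, ncol = 1))
  b1 <- dense_backward(model$classifier$fc1, cache$f1, b2$dX)
  grads <- list(clf = list(fc1 = b1$grads, fc2 = b2$grads))
  if (!is.null(model$extractor) && !isTRUE(model$frozen)) {
    i0 <- cache$extra_cols
    dfused <- b1$dX[, (i0 + 1):(i0 + cache$fused_cols), drop = FALSE]
    grads$ext <- extractor_backward(model$extractor, model$cfg, cache$ecache, dfused)
  }
  grads
}

#' Predict interaction probabilities
#'
#' @param object A trained (or untrained) `"phic_model"`.
#' @param bundles A `"feature_bundles"` object matching the model config.
#' @param batch_size Forward-pass batch size (memory control).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.phic_model <- function(object, bundles, batch_size = 256L, ...) {
  n <- bundles$meta$n %||% length(bundles$label)
  p <- numeric(n)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    bb <- subset_bundles(bundles, ix)
    extra <- NULL
    if (identical(object$mode, "multitask")) {
      extra <- extractor_forward(object$shared$extractor, object$shared$cfg,
                                 bb, train = FALSE)$fused
    }
    p[ix] <- model_forward(object, bb, train = FALSE, extra = extra)$p
  }
  p
}

#' Extract fused (post-pooling, pre-classifier) feature vectors
#'
#' For a base/transfer model this is the global-average-pooled output of the
#' fusion convolution; for a multi-task model the common (shared) and
#' private features are concatenated column-wise in that order.
#'
#' @param model A `"phic_model"`.
#' @param bundles A `"feature_bundles"` object.
#' @param batch_size Forward-pass batch size.
#' @return A numeric matrix, one row per interaction.
#' @export
extract_features <- function(model, bundles, batch_size = 256L) {
  if (is.null(model$extractor) && is.null(model$shared)) {
    stopf("model has no convolutional feature extractor (distance-only ablation)")
  }
  n <- bundles$meta$n %||% length(bundles$label)
  out <- NULL
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    bb <- subset_bundles(bundles, ix)
    fs <- NULL
    if (identical(model$mode, "multitask")) {
      fs <- extractor_forward(model$shared$extractor, model$shared$cfg,
                              bb, train = FALSE)$fused
    }
    fp <- if (!is.null(model$extractor)) {
      extractor_forward(model$extractor, model$cfg, bb, train = FALSE)$fused
    } else NULL
    row <- cbind(fs, fp)
    out <- rbind(out, row)
  }
  out
}

#' Freeze or unfreeze a model's feature extractor
#'
#' A frozen extractor receives no gradient updates during subsequent
#' training; only the classifier head is trained.
#'
#' @param model A `"phic_model"`.
#' @return The model with the freeze flag set/cleared.
#' @export
freeze_extractor <- function(model) { model$frozen <- TRUE; model }

#' @rdname freeze_extractor
#' @export
unfreeze_extractor <- function(model) { model$frozen <- FALSE; model }

# ---- introspection ---------------------------------------------------------

#' Layer table of a model
#'
#' One row per convolution/dense layer with its geometry: filters, kernel,
#' stride, dilation, input channels and output spatial shape. Used by tests
#' to assert architecture constants (4 conv layers per dense block with
#' filters 64/32/16/16 and dilations 1-4; classifier hidden width 256).
#'
#' @param model A `"phic_model"`.
#' @return A data.frame.
#' @export
describe_model <- function(model) {
  rows <- list()
  add <- function(path, layer, type, L = NULL) {
    if (!is.null(L) && identical(L$type, "conv")) {
      pl <- L$plan
      rows[[length(rows) + 1]] <<- data.frame(
        path = path, layer = layer, type = type,
        filters = L$filters, kernel = paste(pl$kernel, collapse = "x"),
        stride = paste(pl$stride, collapse = "x"), dilation = pl$dilation,
        in_channels = pl$C, out_h = pl$oh, out_w = pl$ow,
        stringsAsFactors = FALSE
      )
    } else {
      rows[[length(rows) + 1]] <<- data.frame(
        path = path, layer = layer, type = type,
        filters = ncol(L$W), kernel = NA, stride = NA, dilation = NA,
        in_channels = nrow(L$W), out_h = NA, out_w = NA,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(model$extractor)) {
    for (mod in names(model$extractor$blocks)) {
      b <- model$extractor$blocks[[mod]]
      for (k in seq_along(b$layers)) add(mod, k, "conv", b$layers[[k]])
    }
    add("fusion", 1L, "conv", model$extractor$fusion)
  }
  add("classifier", 1L, "dense", model$classifier$fc1)
  add("classifier", 2L, "dense", model$classifier$fc2)
  do.call(rbind, rows)
}

#' @export
print.phic_model <- function(x, ...) {
  cat(sprintf("<phic_model> mode=%s active=%s fused_dim=%d%s\n",
              x$mode, paste(x$cfg$active, collapse = "+"), x$fused_dim,
              if (isTRUE(x$frozen)) " [frozen extractor]" else ""))
  print(describe_model(x))
  invisible(x)
}

# ---- parameter plumbing ----------------------------------------------------

collect_params <- function(model) {
  out <- list()
  if (!is.null(model$extractor)) {
    for (mod in names(model$extractor$blocks)) {
      ls <- model$extractor$blocks[[mod]]$layers
      for (k in seq_along(ls)) {
        for (t in c("W", "gamma", "beta", "alpha")) {
          out[[paste("ext", mod, k, t, sep = ".")]] <- ls[[k]][[t]]
        }
      }
    }
    for (t in c("W", "gamma", "beta", "alpha")) {
      out[[paste("ext", "fusion", 1, t, sep = ".")]] <- model$extractor$fusion[[t]]
    }
  }
  for (f in c("fc1", "fc2")) {
    for (t in c("W", "b")) out[[paste("clf", f, t, sep = ".")]] <- model$classifier[[f]][[t]]
  }
  out
}

assign_params <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "ext") {
      if (parts[2] == "fusion") {
        model$extractor$fusion[[parts[4]]] <- params[[nm]]
      } else {
        model$extractor$blocks[[parts[2]]]$layers[[as.integer(parts[3])]][[parts[4]]] <- params[[nm]]
      }
    } else {
      model$classifier[[parts[2]]][[parts[3]]] <- params[[nm]]
    }
  }
  model
}

collect_grads <- function(model, grads) {
  out <- list()
  if (!is.null(grads$ext)) {
    for (mod in setdiff(names(grads$ext), "fusion")) {
      for (k in seq_along(grads$ext[[mod]])) {
        for (t in c("W", "gamma", "beta", "alpha")) {
          out[[paste("ext", mod, k, t, sep = ".")]] <- grads$ext[[mod]][[k]][[t]]
        }
      }
    }
    for (t in c("W", "gamma", "beta", "alpha")) {
      out[[paste("ext", "fusion", 1, t, sep = ".")]] <- grads$ext$fusion[[t]]
    }
  }
  for (f in c("fc1", "fc2")) {
    for (t in c("W", "b")) out[[paste("clf", f, t, sep = ".")]] <- grads$clf[[f]][[t]]
  }
  out
}

collect_bn_state <- function(model) {
  out <- list()
  if (!is.null(model$extractor)) {
    for (mod in names(model$extractor$blocks)) {
      ls <- model$extractor$blocks[[mod]]$layers
      for (k in seq_along(ls)) {
        for (t in c("rmean", "rvar")) {
          out[[paste("ext", mod, k, t, sep = ".")]] <- ls[[k]][[t]]
        }
      }
    }
    for (t in c("rmean", "rvar")) {
      out[[paste("ext", "fusion", 1, t, sep = ".")]] <- model$extractor$fusion[[t]]
    }
  }
  out
}

assign_bn_state <- function(model, state) {
  for (nm in names(state)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[2] == "fusion") {
      model$extractor$fusion[[parts[4]]] <- state[[nm]]
    } else {
      model$extractor$blocks[[parts[2]]]$layers[[as.integer(parts[3])]][[parts[4]]] <- state[[nm]]
    }
  }
  model
}

# ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a directory with a plain-text JSON manifest (the model
#' config and mode) and a JSON weights file (parameters and batch-norm
#' statistics, full precision). `load_model` rebuilds the network from the
#' manifest and restores the weights; predictions round-trip exactly up to
#' floating-point serialization.
#'
#' @param model A `"phic_model"`.
#' @param dir Checkpoint directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(mode = model$mode, frozen = isTRUE(model$frozen),
                   cfg = unclass(model$cfg),
                   shared_cfg = if (!is.null(model$shared)) unclass(model$shared$cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  dump_weights <- function(m) {
    list(params = lapply(collect_params(m), as.vector),
         dims = lapply(collect_params(m), function(p) dim(p) %||% length(p)),
         bn = collect_bn_state(m))
  }
  w <- dump_weights(model)
  if (!is.null(model$shared)) {
    w$shared <- dump_weights(list(extractor = model$shared$extractor,
                                  classifier = model$shared$head))
  }
  jsonlite::write_json(w, file.path(dir, "weights.json"), digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  w <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  restore_cfg <- function(c) { class(c) <- "model_config"; c }
  restore <- function(skel, wt) {
    params <- wt$params
    for (nm in names(params)) {
      d <- wt$dims[[nm]]
      if (length(d) > 1) dim(params[[nm]]) <- d
    }
    skel <- assign_params(skel, params)
    if (length(wt$bn) > 0) skel <- assign_bn_state(skel, wt$bn)
    skel
  }
  cfg <- restore_cfg(manifest$cfg)
  model <- restore(build_model(cfg), w)
  model$mode <- manifest$mode
  model$frozen <- isTRUE(manifest$frozen)
  if (identical(manifest$mode, "multitask")) {
    scfg <- restore_cfg(manifest$shared_cfg)
    sk <- restore(build_model(scfg), w$shared)
    model$shared <- list(cfg = scfg, extractor = sk$extractor, head = sk$classifier)
  }
  model
}
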