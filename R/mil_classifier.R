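#' Configuration of the multiple-instance classifier
#'
#' Bags of `bag_size` tiles share their slide's label; `tiles_per_slide`
#' random tiles are drawn per slide and partitioned into consecutive bags,
#' so each slide yields `tiles_per_slide / bag_size` bags. Defaults mirror a
#' full-scale training recipe (bags of 100 from 200 tiles per slide, AdamW
#' at 1e-3, batches of 64 tiles, 100 epochs with patience 20, flip
#' augmentation, ImageNet channel statistics); scaled-down experiments pass
#' smaller values.
#'
#' @param bag_size tiles per bag.
#' @param tiles_per_slide random tiles drawn per slide; must be a multiple
#'   of `bag_size`. Slides with fewer stored tiles are topped up by sampling
#'   with replacement.
#' @param backbone feature extractor; this build provides `"small_cnn"`
#'   (frozen random 3-block CNN, 32-dim descriptor).
#' @param head_width width of the feature entering the classification head
#'   in a large-backbone setting; informational for `small_cnn`, where the
#'   head consumes the `feature_dim`-wide projection directly.
#' @param feature_dim width D of the trainable projection layer feeding the
#'   head (the "last convolutional layer" of the network: a 1x1 projection
#'   of the frozen descriptor).
#' @param learning_rate,weight_decay AdamW settings.
#' @param batch_size tiles per optimizer step; bags are grouped so each
#'   step covers `max(1, batch_size / bag_size)` whole bags.
#' @param max_epochs,patience early-stopping schedule: training stops once
#'   the validation metric (patient-level accuracy) has not improved for
#'   `patience` consecutive epochs.
#' @param augment_flips apply independent horizontal/vertical flips with
#'   probability 0.5 each during training.
#' @param input_mean,input_std per-channel standardization applied after
#'   scaling tiles to \[0, 1\] (defaults: ImageNet statistics).
#' @param normalizer optional `reinhard_fit` applied to tiles before
#'   standardization (stain normalization at train/inference time), or NULL.
#' @param seed master seed controlling initialization, bag sampling and
#'   flips; fixing it makes training fully reproducible.
#' @return A `model_config`.
#' @export
model_config <- function(bag_size = 100L,
                         tiles_per_slide = 200L,
                         backbone = "small_cnn",
                         head_width = 2048L,
                         feature_dim = 64L,
                         learning_rate = 1e-3,
                         weight_decay = 0.01,
                         batch_size = 64L,
                         max_epochs = 100L,
                         patience = 20L,
                         augment_flips = TRUE,
                         input_mean = c(0.485, 0.456, 0.406),
                         input_std = c(0.229, 0.224, 0.225),
                         normalizer = NULL,
                         seed = 1L) {
  if (tiles_per_slide %% bag_size != 0) {
    abort_wsimil("tiles_per_slide must be a multiple of bag_size", "wsimil_config_error")
  }
  if (patience >= max_epochs) {
    abort_wsimil("patience must be smaller than max_epochs", "wsimil_config_error")
  }
  if (learning_rate <= 0 || batch_size <= 0 || bag_size <= 0) {
    abort_wsimil("rates and sizes must be positive", "wsimil_config_error")
  }
  structure(
    list(
      bag_size = as.integer(bag_size), tiles_per_slide = as.integer(tiles_per_slide),
      backbone = backbone, head_width = as.integer(head_width),
      feature_dim = as.integer(feature_dim),
      learning_rate = learning_rate, weight_decay = weight_decay,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      augment_flips = isTRUE(augment_flips),
      input_mean = input_mean, input_std = input_std,
      normalizer = normalizer, seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Preprocess a tile for the network
#'
#' Optional stain normalization (if `config$normalizer` is set), scaling to
#' \[0, 1\], per-channel standardization, and — during training only —
#' independent horizontal and vertical flips with probability 0.5 each
#' (drawn from the current RNG stream). Inference applies no flips and is
#' deterministic.
#'
#' @param tile H x W x 3 RGB array in \[0, 255\].
#' @param config a [model_config()].
#' @param training draw random flips?
#' @return H x W x 3 double array.
#' @export
preprocess_tile <- function(tile, config, training = FALSE) {
  if (!is.null(config$normalizer)) {
    tile <- apply_reinhard(tile, config$normalizer)
  }
  x <- array(as.numeric(tile) / 255, dim = dim(tile))
  for (ch in 1:3) {
    x[, , ch] <- (x[, , ch] - config$input_mean[ch]) / config$input_std[ch]
  }
  if (training && config$augment_flips) {
    x <- flip_tile(x, horizontal = stats::runif(1) < 0.5,
                   vertical = stats::runif(1) < 0.5)
  }
  x
}

#' Flip a tile array
#' @param x H x W x 3 array.
#' @param horizontal reverse columns; @param vertical reverse rows.
#' @return Flipped array.
#' @export
flip_tile <- function(x, horizontal = FALSE, vertical = FALSE) {
  if (horizontal) x <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  if (vertical) x <- x[rev(seq_len(dim(x)[1L])), , , drop = FALSE]
  x
}

# Draw tile indices for one slide: min(tiles_per_slide, n) distinct tiles,
# topped up with replacement to exactly tiles_per_slide, partitioned into
# consecutive bags of bag_size. Pure index logic, shared by the public
# sampler and the training loop.
sample_bag_indices <- function(n_tiles, config) {
  m <- min(config$tiles_per_slide, n_tiles)
  idx <- sample.int(n_tiles, m)
  short <- config$tiles_per_slide - m
  if (short > 0L) {
    idx <- c(idx, sample.int(n_tiles, short, replace = TRUE))
  }
  split(idx, rep(seq_len(config$tiles_per_slide / config$bag_size),
                 each = config$bag_size))
}

#' Sample bags of tiles from a slide's tile store
#'
#' Draws `tiles_per_slide` tiles (without replacement while the store
#' lasts, then with replacement) and partitions them into consecutive bags
#' of `bag_size`, each carrying the slide's global label.
#'
#' @param store a `tile_store`.
#' @param config a [model_config()].
#' @param seed sampling seed.
#' @param label optional slide label attached to every bag.
#' @return List of `bag` objects: `slide_id`, `label`, `tile_idx` (indices
#'   into the store), `tiles` (bag_size x ts x ts x 3 array), `bag_index`.
#'   An empty store yields an empty list with a warning.
#' @export
sample_bags <- function(store, config, seed = 1L, label = NULL) {
  if (store$n_kept == 0L) {
    warning("empty tile store for slide ", store$slide_id, "; no bags")
    return(list())
  }
  bag_idx <- with_seed(seed, sample_bag_indices(store$n_kept, config))
  lapply(seq_along(bag_idx), function(b) {
    idx <- bag_idx[[b]]
    structure(
      list(
        slide_id = store$slide_id, label = label, tile_idx = idx,
        tiles = store$tiles[idx, , , , drop = FALSE], bag_index = b
      ),
      class = "bag"
    )
  })
}

# ---- trainable part: 1x1 projection layer + linear head ------------------

init_params <- function(config, P) {
  D <- config$feature_dim
  xavier <- function(fi, fo) stats::rnorm(fi * fo, 0, sqrt(2 / (fi + fo)))
  with_seed(derive_seed(config$seed, "init"), list(
    Wp = matrix(xavier(P, D), D, P), bp = rep(0, D),
    Wh = matrix(xavier(D, 2), 2, D), bh = rep(0, 2),
    # backbone-descriptor standardization (estimated from the training
    # tiles at the start of training, then held fixed; not optimized)
    feat_mean = rep(0, P), feat_sd = rep(1, P)
  ))
}

# Forward a P x n feature matrix (one bag) through standardization,
# projection and head.
bag_forward_z <- function(params, Z) {
  Zs <- (Z - params$feat_mean) / params$feat_sd
  Hm <- params$Wp %*% Zs + params$bp
  Hm[Hm < 0] <- 0
  f <- rowMeans(Hm)
  logits <- as.numeric(params$Wh %*% f + params$bh)
  list(Zs = Zs, Hm = Hm, pooled = f, probs = softmax(logits))
}

bag_backward_z <- function(params, Z, fwd, y_onehot) {
  n <- ncol(fwd$Zs)
  dlog <- fwd$probs - y_onehot
  dWh <- outer(dlog, fwd$pooled)
  df <- as.numeric(t(params$Wh) %*% dlog)
  dHm <- matrix(df / n, length(df), n) * (fwd$Hm > 0)
  list(Wp = dHm %*% t(fwd$Zs), bp = rowSums(dHm), Wh = dWh, bh = dlog)
}

# Per-dimension mean/sd of the training-set descriptors (zero-variance
# dimensions keep scale 1 so dead backbone channels stay inert).
descriptor_stats <- function(train_feats) {
  allZ <- do.call(cbind, lapply(train_feats, `[[`, "00"))
  mu <- rowMeans(allZ)
  sdv <- apply(allZ, 1L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  list(mean = mu, sd = sdv)
}

adamw_step <- function(params, grads, state, config) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - config$learning_rate *
      (mhat / (sqrt(vhat) + eps) + config$weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Forward a bag through the model
#'
#' Per-tile features are extracted with the frozen backbone, projected by
#' the trainable layer, arithmetic-mean pooled over the bag, and passed
#' through the linear head. Mean pooling makes the output invariant to the
#' order of tiles within the bag.
#'
#' @param bag a `bag` from [sample_bags()] (its `tiles` array is used).
#' @param model a `mil_model` (trained or freshly initialized via
#'   [init_mil_model()]).
#' @return List with `pooled_feature` (length `feature_dim`) and
#'   `class_probs` (named, control/tumor, sums to 1).
#' @export
forward_bag <- function(bag, model) {
  config <- model$config
  Z <- vapply(seq_along(bag$tile_idx), function(i) {
    tile <- array(bag$tiles[i, , , ], dim = dim(bag$tiles)[2:4])
    backbone_features(model$backbone, preprocess_tile(tile, config))
  }, numeric(model$backbone$feature_dim))
  Z <- matrix(Z, nrow = model$backbone$feature_dim)
  fwd <- bag_forward_z(model$params, Z)
  list(pooled_feature = fwd$pooled,
       class_probs = stats::setNames(fwd$probs, c("control", "tumor")))
}

#' Initialize an untrained MIL model
#'
#' @param config a [model_config()].
#' @param backbone optional pre-built backbone (shared across models); by
#'   default initialized from the config seed.
#' @return A `mil_model` with Xavier-initialized projection/head weights.
#' @export
init_mil_model <- function(config, backbone = NULL) {
  backbone <- backbone %||% init_backbone(config)
  structure(
    list(backbone = backbone, params = init_params(config, backbone$feature_dim),
         config = config, history = NULL, best_epoch = NA_integer_,
         trained = FALSE, classes = c("control", "tumor")),
    class = "mil_model"
  )
}

#' Early-stopping bookkeeping
#'
#' Scans a validation-metric trace with the strict-improvement rule used by
#' [train_model()]: the best epoch is the earliest maximum, and training
#' stops after `patience` consecutive epochs without improvement (i.e., at
#' epoch `best_epoch + patience`), or at the end of the trace.
#'
#' @param metrics numeric vector, one validation metric value per epoch.
#' @param patience non-improving epochs tolerated.
#' @return List with `best_epoch` and `stop_epoch`.
#' @export
early_stop_epoch <- function(metrics, patience) {
  best <- -Inf; best_epoch <- 0L
  for (e in seq_along(metrics)) {
    if (metrics[e] > best) {
      best <- metrics[e]; best_epoch <- e
    }
    if (e - best_epoch >= patience) {
      return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(metrics))
}

# Per-slide feature tables under the frozen backbone: for each tile the
# descriptor of the unflipped tile and its three flip variants. Computed
# once per backbone and reused across epochs/folds (flips select a column
# set, they never require re-running the convolutions).
flip_variants <- c("00", "10", "01", "11")  # (horizontal, vertical) flags

slide_features <- function(backbone, store, config, variants = flip_variants) {
  P <- backbone$feature_dim
  n <- store$n_kept
  out <- lapply(variants, function(v) matrix(0, P, n))
  names(out) <- variants
  for (i in seq_len(n)) {
    chans <- pooled_tile_channels(backbone, store_tile(store, i), config)
    for (v in variants) {
      h <- substr(v, 1, 1) == "1"; vv <- substr(v, 2, 2) == "1"
      out[[v]][, i] <- backbone_forward_pooled(backbone, flip_channels(chans, h, vv))
    }
  }
  out
}

# Resolve the feature table of a slide, computing and caching on demand.
# `cache` is an environment: cache[[slide_id]] = list of variant matrices.
features_for_slide <- function(cache, slide_id, backbone, config, store_fn,
                               variants = flip_variants) {
  got <- cache[[slide_id]]
  if (is.null(got) || !all(variants %in% names(got))) {
    store <- store_fn(slide_id)
    got <- slide_features(backbone, store, config, variants)
    cache[[slide_id]] <- got
  }
  got
}

# Deterministic store accessor for a manifest (reads store_path files).
manifest_store_fn <- function(manifest) {
  function(slide_id) {
    path <- manifest$store_path[manifest$slide_id == slide_id][1L]
    read_tile_store(path)
  }
}

label_onehot <- function(class_label) {
  if (class_label == "tumor") c(0, 1) else c(1, 0)
}

# Deterministic slide-level probabilities from cached features.
slide_probs_from_features <- function(params, feats, config, seed) {
  n <- ncol(feats[["00"]])
  if (n == 0L) {
    abort_wsimil("cannot predict a slide with an empty tile store",
                 "wsimil_empty_store")
  }
  bag_idx <- with_seed(seed, sample_bag_indices(n, config))
  probs <- vapply(bag_idx, function(idx) {
    bag_forward_z(params, feats[["00"]][, idx, drop = FALSE])$probs
  }, numeric(2L))
  rowMeans(matrix(probs, nrow = 2L))
}

# Patient-level accuracy of a manifest given per-slide probabilities
# (named list slide_id -> 2-vector), aggregating (patient, class) entities.
entity_accuracy <- function(manifest, probs_by_slide) {
  ent <- unique(manifest[, c("patient_id", "class_label")])
  correct <- vapply(seq_len(nrow(ent)), function(i) {
    sl <- manifest$slide_id[manifest$patient_id == ent$patient_id[i] &
                              manifest$class_label == ent$class_label[i]]
    p <- aggregate_patient_probability(probs_by_slide[sl])
    pred <- if (p[2L] >= p[1L]) "tumor" else "control"
    pred == ent$class_label[i]
  }, logical(1L))
  mean(correct)
}

#' Train the weakly-supervised MIL classifier
#'
#' Optimizes bag-level cross-entropy with AdamW over the trainable
#' projection layer and linear head; the backbone stays frozen. Each epoch
#' re-draws bags and flip augmentations per slide, groups bags into
#' optimizer steps of `max(1, batch_size / bag_size)` bags, and evaluates
#' patient-level accuracy on the validation set. Early stopping restores
#' the parameters of the best validation epoch. Fully reproducible given
#' `config$seed`.
#'
#' @param train,val lists with elements `manifest` (slide rows: slide_id,
#'   patient_id, class_label, store_path) describing disjoint patient sets.
#' @param config a [model_config()].
#' @param backbone optional shared frozen backbone.
#' @param feature_cache optional environment of precomputed per-slide
#'   feature tables (filled as needed).
#' @return A trained `mil_model` with `history` (per-epoch train loss,
#'   validation loss and accuracy) and `best_epoch`.
#' @export
train_model <- function(train, val, config, backbone = NULL,
                        feature_cache = NULL) {
  tm <- train$manifest; vm <- val$manifest
  if (is.null(tm) || nrow(tm) == 0L || is.null(vm) || nrow(vm) == 0L) {
    abort_wsimil("empty training or validation set", "wsimil_config_error")
  }
  if (length(unique(vm$class_label)) < 2L) {
    abort_wsimil("validation set must contain both classes", "wsimil_config_error")
  }
  common <- intersect(unique(tm$patient_id), unique(vm$patient_id))
  if (length(common)) {
    abort_wsimil(paste0("train/val patient overlap: ", paste(common, collapse = ", ")),
                 "wsimil_config_error")
  }
  backbone <- backbone %||% init_backbone(config)
  cache <- feature_cache %||% new.env(parent = emptyenv())
  store_fn_t <- manifest_store_fn(tm)
  store_fn_v <- manifest_store_fn(vm)

  train_feats <- lapply(tm$slide_id, function(s) {
    f <- features_for_slide(cache, s, backbone, config, store_fn_t)
    if (ncol(f[["00"]]) == 0L) {
      warning("slide ", s, " has an empty tile store; excluded from training")
      return(NULL)
    }
    f
  })
  names(train_feats) <- tm$slide_id
  keep <- !vapply(train_feats, is.null, logical(1L))
  tm <- tm[keep, , drop = FALSE]
  train_feats <- train_feats[keep]
  val_feats <- lapply(vm$slide_id, function(s) {
    features_for_slide(cache, s, backbone, config, store_fn_v, variants = "00")
  })
  names(val_feats) <- vm$slide_id
  val_keep <- vapply(val_feats, function(f) ncol(f[["00"]]) > 0L, logical(1L))
  if (!all(val_keep)) {
    warning("validation slide(s) with empty tile stores excluded: ",
            paste(vm$slide_id[!val_keep], collapse = ", "))
    vm <- vm[val_keep, , drop = FALSE]
    val_feats <- val_feats[val_keep]
    if (nrow(vm) == 0L || length(unique(vm$class_label)) < 2L) {
      abort_wsimil("validation set lost a class to empty tile stores",
                   "wsimil_config_error")
    }
  }

  params <- init_params(config, backbone$feature_dim)
  fs <- descriptor_stats(train_feats)
  params$feat_mean <- fs$mean
  params$feat_sd <- fs$sd
  state <- list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  bags_per_step <- max(1L, config$batch_size %/% config$bag_size)
  # patience counts strict improvements of the validation metric; among
  # epochs tied on the metric the snapshot with the lowest validation loss
  # is kept (small validation sets saturate the metric early, and the
  # lower-loss model has the wider margins)
  best_acc <- -Inf; best_loss <- Inf; best_epoch <- 0L; best_params <- params
  snapshot_epoch <- 0L
  history <- list()

  for (epoch in seq_len(config$max_epochs)) {
    epoch_plan <- with_seed(derive_seed(config$seed, "epoch", epoch), {
      bags <- list()
      for (s in tm$slide_id) {
        n <- ncol(train_feats[[s]][["00"]])
        for (idx in sample_bag_indices(n, config)) {
          variants <- if (config$augment_flips) {
            paste0(
              ifelse(stats::runif(length(idx)) < 0.5, "1", "0"),
              ifelse(stats::runif(length(idx)) < 0.5, "1", "0")
            )
          } else {
            rep("00", length(idx))
          }
          bags[[length(bags) + 1L]] <- list(slide = s, idx = idx, variants = variants)
        }
      }
      bags[sample.int(length(bags))]
    })

    losses <- numeric(length(epoch_plan))
    step_groups <- split(seq_along(epoch_plan),
                         (seq_along(epoch_plan) - 1L) %/% bags_per_step)
    bi <- 0L
    for (grp in step_groups) {
      grads <- NULL
      for (g in grp) {
        plan <- epoch_plan[[g]]
        feats <- train_feats[[plan$slide]]
        Z <- matrix(0, backbone$feature_dim, length(plan$idx))
        for (v in unique(plan$variants)) {
          sel <- plan$variants == v
          Z[, sel] <- feats[[v]][, plan$idx[sel], drop = FALSE]
        }
        y <- label_onehot(tm$class_label[tm$slide_id == plan$slide][1L])
        fwd <- bag_forward_z(params, Z)
        bi <- bi + 1L
        losses[bi] <- -log(max(sum(fwd$probs * y), 1e-12))
        gr <- bag_backward_z(params, Z, fwd, y)
        grads <- if (is.null(grads)) gr else Map(`+`, grads, gr)
      }
      grads <- lapply(grads, function(g) g / length(grp))
      upd <- adamw_step(params, grads, state, config)
      params <- upd$params; state <- upd$state
    }

    val_probs <- lapply(vm$slide_id, function(s) {
      slide_probs_from_features(params, val_feats[[s]], config,
                                derive_seed(config$seed, "valbags", s))
    })
    names(val_probs) <- vm$slide_id
    val_loss <- mean(vapply(vm$slide_id, function(s) {
      y <- label_onehot(vm$class_label[vm$slide_id == s][1L])
      -log(max(sum(val_probs[[s]] * y), 1e-12))
    }, numeric(1L)))
    val_acc <- entity_accuracy(vm, val_probs)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(losses),
      val_loss = val_loss, val_acc = val_acc
    )
    if (val_acc > best_acc) {
      best_acc <- val_acc; best_epoch <- epoch
      best_loss <- val_loss; best_params <- params; snapshot_epoch <- epoch
    } else if (val_acc == best_acc && val_loss < best_loss) {
      best_loss <- val_loss; best_params <- params; snapshot_epoch <- epoch
    }
    if (epoch - best_epoch >= config$patience) break
  }

  structure(
    list(backbone = backbone, params = best_params, config = config,
         history = do.call(rbind, history), best_epoch = best_epoch,
         snapshot_epoch = snapshot_epoch,
         trained = TRUE, classes = c("control", "tumor")),
    class = "mil_model"
  )
}

#' Predict class probabilities for one slide
#'
#' Slide-level probabilities are the arithmetic mean of the bag-level
#' probabilities over the slide's bags (the mean of points on the
#' probability simplex stays on the simplex). Per-tile probabilities run
#' the head on each tile's un-pooled projected feature (a bag of one),
#' which is what a tile-level prediction heatmap would visualize.
#'
#' @param model a trained `mil_model`.
#' @param store the slide's `tile_store`.
#' @param config configuration (defaults to the model's).
#' @param seed bag-sampling seed.
#' @return List with `slide_probs` (named 2-vector) and `per_tile_probs`
#'   (n_kept x 2 matrix, rows on the simplex).
#' @export
predict_slide <- function(model, store, config = model$config, seed = 1L) {
  if (store$n_kept == 0L) {
    abort_wsimil(paste0("empty tile store for slide ", store$slide_id),
                 "wsimil_empty_store")
  }
  feats <- slide_features(model$backbone, store, config, variants = "00")
  slide_probs <- slide_probs_from_features(model$params, feats, config, seed)
  Z <- feats[["00"]]
  per_tile <- t(vapply(seq_len(ncol(Z)), function(i) {
    bag_forward_z(model$params, Z[, i, drop = FALSE])$probs
  }, numeric(2L)))
  colnames(per_tile) <- c("control", "tumor")
  list(
    slide_probs = stats::setNames(slide_probs, c("control", "tumor")),
    per_tile_probs = per_tile
  )
}
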