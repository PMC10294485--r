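# Bag sampling, preprocessing, the pooled forward pass, training contracts
# (frozen backbone, early stopping, determinism) and slide prediction.

test_that("configuration invariants are enforced", {
  expect_error(model_config(bag_size = 8, tiles_per_slide = 20),
               class = "wsimil_config_error")
  expect_error(model_config(max_epochs = 10, patience = 10),
               class = "wsimil_config_error")
  expect_error(model_config(learning_rate = 0), class = "wsimil_config_error")
  expect_error(init_backbone(model_config(backbone = "resnet50_imagenet")),
               class = "wsimil_config_error")
})

test_that("bag sampling draws without replacement and tops up when short", {
  store <- small_store()
  n <- store$n_kept  # 4 tiles on a 512x512 slide

  # exhaustive draw: one bag containing every tile exactly once
  cfg1 <- model_config(bag_size = n, tiles_per_slide = n, seed = 1)
  bags <- sample_bags(store, cfg1, seed = 5)
  expect_length(bags, 1L)
  expect_setequal(bags[[1]]$tile_idx, seq_len(n))

  # demand 4x the store: every distinct tile appears, duplicates fill the rest
  cfg2 <- model_config(bag_size = 2L * n, tiles_per_slide = 4L * n, seed = 1)
  bags2 <- sample_bags(store, cfg2, seed = 5)
  expect_length(bags2, 2L)
  drawn <- unlist(lapply(bags2, `[[`, "tile_idx"))
  expect_length(drawn, 4L * n)
  expect_setequal(unique(drawn), seq_len(n))
  # duplicate slots = total - distinct
  expect_gte(length(drawn) - length(unique(drawn)), 3L * n)

  # determinism
  bags3 <- sample_bags(store, cfg2, seed = 5)
  expect_identical(lapply(bags2, `[[`, "tile_idx"), lapply(bags3, `[[`, "tile_idx"))

  empty <- structure(
    list(slide_id = "e", tiles = array(integer(), c(0L, 256L, 256L, 3L)),
         tile_ids = character(), origins = matrix(integer(), 0L, 2L),
         background_fraction = numeric(), contrast_stat = numeric(),
         n_candidates = 0L, n_kept = 0L, extraction_seed = 1L, undersized = FALSE),
    class = "tile_store")
  expect_warning(b <- sample_bags(empty, cfg1), regexp = "empty")
  expect_length(b, 0L)
})

test_that("tile preprocessing standardizes, flips stochastically, and is an involution", {
  tile <- random_rgb(64L, 64L, seed = 7L)
  cfg <- model_config(input_mean = c(0, 0, 0), input_std = c(1, 1, 1))
  x <- preprocess_tile(tile, cfg)
  expect_equal(x, array(as.numeric(tile) / 255, dim = dim(tile)))

  # inference path is deterministic
  cfg2 <- model_config(seed = 3)
  expect_identical(preprocess_tile(tile, cfg2), preprocess_tile(tile, cfg2))

  # double flip is the identity
  expect_identical(flip_tile(flip_tile(x, horizontal = TRUE), horizontal = TRUE), x)
  expect_identical(flip_tile(flip_tile(x, vertical = TRUE), vertical = TRUE), x)

  # training flips hit both states under a fixed stream
  states <- wsimil:::with_seed(42, replicate(20, {
    y <- preprocess_tile(tile, cfg, training = TRUE)
    identical(y, x)
  }))
  expect_true(any(states) && !all(states))
})

test_that("forward_bag is permutation invariant and pools by the arithmetic mean", {
  store <- small_store()
  cfg <- model_config(bag_size = 4L, tiles_per_slide = 4L, seed = 2)
  model <- init_mil_model(cfg)
  bags <- sample_bags(store, cfg, seed = 9)
  out <- forward_bag(bags[[1]], model)
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-6)

  perm <- bags[[1]]
  o <- c(3, 1, 4, 2)
  perm$tile_idx <- perm$tile_idx[o]
  perm$tiles <- perm$tiles[o, , , , drop = FALSE]
  out_p <- forward_bag(perm, model)
  expect_equal(out_p$pooled_feature, out$pooled_feature, tolerance = 1e-5)
  expect_equal(out_p$class_probs, out$class_probs, tolerance = 1e-5)

  # a bag of copies of one tile pools to that tile's own feature
  mono <- bags[[1]]
  mono$tile_idx <- rep(mono$tile_idx[1], 4)
  mono$tiles <- mono$tiles[rep(1, 4), , , , drop = FALSE]
  single <- mono; single$tile_idx <- mono$tile_idx[1]
  single$tiles <- mono$tiles[1, , , , drop = FALSE]
  expect_equal(forward_bag(mono, model)$pooled_feature,
               forward_bag(single, model)$pooled_feature, tolerance = 1e-9)

  # pooling equals the brute-force route: average per-tile features, then head
  Z <- vapply(seq_len(4), function(i) {
    backbone_features(model$backbone,
                      preprocess_tile(store$tiles[bags[[1]]$tile_idx[i], , , ], cfg))
  }, numeric(model$backbone$feature_dim))
  Zs <- (Z - model$params$feat_mean) / model$params$feat_sd
  H <- pmax(model$params$Wp %*% Zs + model$params$bp, 0)
  manual <- rowMeans(H)
  expect_equal(out$pooled_feature, manual, tolerance = 1e-5)
})

test_that("early stopping fires at best_epoch + patience on a scripted metric", {
  # strict improvement at epochs 1..3, then a plateau
  metrics <- c(0.5, 0.7, 0.9, rep(0.9, 30))
  res <- early_stop_epoch(metrics, patience = 5L)
  expect_equal(res$best_epoch, 3L)
  expect_equal(res$stop_epoch, 8L)

  # monotone improvement never stops early
  res2 <- early_stop_epoch(seq(0.1, 0.9, length.out = 9), patience = 3L)
  expect_equal(res2$best_epoch, 9L)
  expect_equal(res2$stop_epoch, 9L)
})

test_that("training freezes the backbone, stops on schedule and reproduces bit-for-bit", {
  co <- small_tiled_cohort()
  cfg <- model_config(bag_size = 4L, tiles_per_slide = 8L, batch_size = 4L,
                      max_epochs = 6L, patience = 3L, seed = 17L)
  tv <- split_train_val(co$manifest, 0.8, seed = 17L)
  m1 <- train_model(list(manifest = tv$train), list(manifest = tv$val), cfg)

  # frozen parameters byte-identical to a fresh init from the same seed
  fresh <- init_backbone(cfg)
  expect_identical(m1$backbone$W1, fresh$W1)
  expect_identical(m1$backbone$W2, fresh$W2)
  expect_identical(m1$backbone$W3, fresh$W3)

  # early-stopping bookkeeping matches the pure helper on the history
  sched <- early_stop_epoch(m1$history$val_acc, cfg$patience)
  expect_equal(m1$best_epoch, sched$best_epoch)
  expect_equal(nrow(m1$history), sched$stop_epoch)
  expect_lte(nrow(m1$history), cfg$max_epochs)

  # same seed => identical history and parameters
  m2 <- train_model(list(manifest = tv$train), list(manifest = tv$val), cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects degenerate inputs", {
  co <- small_tiled_cohort()
  cfg <- model_config(bag_size = 4L, tiles_per_slide = 8L, max_epochs = 3L,
                      patience = 2L, seed = 1L)
  tv <- split_train_val(co$manifest, 0.8, seed = 1L)
  expect_error(train_model(list(manifest = tv$train[0, ]), list(manifest = tv$val), cfg),
               class = "wsimil_config_error")
  one_class <- tv$val[tv$val$class_label == tv$val$class_label[1], , drop = FALSE]
  expect_error(train_model(list(manifest = tv$train), list(manifest = one_class), cfg),
               class = "wsimil_config_error")
  expect_error(train_model(list(manifest = tv$train), list(manifest = tv$train), cfg),
               class = "wsimil_config_error")  # patient overlap
})

test_that("slide prediction averages bag probabilities and scores every tile", {
  co <- small_tiled_cohort()
  store <- read_tile_store(co$manifest$store_path[1])
  cfg <- model_config(bag_size = 2L, tiles_per_slide = 4L, seed = 23L)
  model <- init_mil_model(cfg)
  model$trained <- TRUE
  pred <- predict_slide(model, store, seed = 4L)
  expect_equal(sum(pred$slide_probs), 1, tolerance = 1e-9)
  expect_equal(dim(pred$per_tile_probs), c(store$n_kept, 2L))
  expect_equal(rowSums(pred$per_tile_probs), rep(1, store$n_kept), tolerance = 1e-9)

  # slide_probs is the arithmetic mean of the per-bag probabilities
  feats <- wsimil:::slide_features(model$backbone, store, cfg, variants = "00")
  bag_idx <- wsimil:::with_seed(4L, wsimil:::sample_bag_indices(store$n_kept, cfg))
  bag_probs <- sapply(bag_idx, function(idx) {
    wsimil:::bag_forward_z(model$params, feats[["00"]][, idx, drop = FALSE])$probs
  })
  expect_equal(unname(pred$slide_probs), rowMeans(bag_probs), tolerance = 1e-9)

  empty <- structure(
    list(slide_id = "e", tiles = array(integer(), c(0L, 256L, 256L, 3L)),
         tile_ids = character(), origins = matrix(integer(), 0L, 2L),
         background_fraction = numeric(), contrast_stat = numeric(),
         n_candidates = 0L, n_kept = 0L, extraction_seed = 1L, undersized = FALSE),
    class = "tile_store")
  expect_error(predict_slide(model, empty), regexp = "e",
               class = "wsimil_empty_store")
})
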