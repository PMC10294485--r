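# Evaluation works on (patient, class) "entities": a patient owning both a
# tumor and a control slide contributes one entity per class (the two
# represent different tissue), but both entities of one patient are always
# co-assigned to the same fold so a patient id never spans train and test.

entity_key <- function(patient_id, class_label) paste(patient_id, class_label, sep = "::")

manifest_entities <- function(manifest) {
  ent <- unique(manifest[, c("patient_id", "class_label")])
  ent <- ent[order(ent$patient_id, ent$class_label), , drop = FALSE]
  rownames(ent) <- NULL
  ent$entity_id <- entity_key(ent$patient_id, ent$class_label)
  ent
}

check_manifest_integrity <- function(manifest) {
  by_pat <- tapply(manifest$dataset_id, manifest$patient_id,
                   function(x) length(unique(x)))
  bad <- names(by_pat)[by_pat > 1L]
  if (length(bad)) {
    abort_wsimil(
      paste0("patient(s) present in multiple datasets: ", paste(bad, collapse = ", ")),
      "wsimil_manifest_error"
    )
  }
  invisible(TRUE)
}

#' Patient-wise stratified (or grouped) cross-validation folds
#'
#' Stratified mode shuffles (patient, class) entities with `seed` and deals
#' them into `k` folds so that per-fold class counts stay within one of
#' perfect stratification. Patients with entities of both classes are
#' assigned first and keep both entities in one fold, so train/test
#' patient-id intersections are empty by construction. Grouped mode builds
#' one fold per distinct value of `group_by` (each test fold is pure in its
#' group), overriding `k`.
#'
#' @param manifest slide manifest (slide_id, patient_id, class_label,
#'   dataset_id, optionally the group column).
#' @param k fold count (stratified mode).
#' @param seed shuffling seed.
#' @param group_by optional manifest column name for grouped folds.
#' @return A `split_plan`: list with `k`, `assignments` (named integer
#'   vector entity_id -> fold), `entities`, `mode`, `seed`.
#' @export
make_patient_folds <- function(manifest, k = 10L, seed = 1L, group_by = NULL) {
  check_manifest_integrity(manifest)
  ent <- manifest_entities(manifest)

  if (!is.null(group_by)) {
    if (!group_by %in% names(manifest)) {
      abort_wsimil(paste0("group column not in manifest: ", group_by),
                   "wsimil_config_error")
    }
    grp_by_pat <- tapply(as.character(manifest[[group_by]]), manifest$patient_id,
                         function(x) unique(x))
    if (any(lengths(grp_by_pat) > 1L)) {
      abort_wsimil("a patient maps to multiple group values", "wsimil_manifest_error")
    }
    groups <- sort(unique(unname(unlist(grp_by_pat))))
    assignments <- stats::setNames(
      match(unlist(grp_by_pat[ent$patient_id]), groups), ent$entity_id
    )
    return(structure(
      list(k = length(groups), assignments = assignments, entities = ent,
           mode = "grouped", groups = groups, seed = seed),
      class = "split_plan"
    ))
  }

  per_class <- table(ent$class_label)
  if (any(per_class < k)) {
    abort_wsimil("k exceeds the number of entities of a class", "wsimil_config_error")
  }
  n_ent_pat <- table(ent$patient_id)
  dual_pats <- names(n_ent_pat)[n_ent_pat == 2L]
  single <- ent[!ent$patient_id %in% dual_pats, , drop = FALSE]

  assignments <- stats::setNames(integer(nrow(ent)), ent$entity_id)
  class_counts <- matrix(0L, nrow = k, ncol = 2L,
                         dimnames = list(NULL, c("control", "tumor")))
  with_seed(seed, {
    # dual patients first, round-robin: adds one entity of each class per fold
    if (length(dual_pats)) {
      dp <- sample(dual_pats)
      folds <- rep_len(seq_len(k), length(dp))
      for (i in seq_along(dp)) {
        assignments[entity_key(dp[i], "control")] <- folds[i]
        assignments[entity_key(dp[i], "tumor")] <- folds[i]
        class_counts[folds[i], ] <- class_counts[folds[i], ] + 1L
      }
    }
    # remaining entities per class: greedy to the emptiest fold of that class
    for (cl in c("control", "tumor")) {
      ids <- single$entity_id[single$class_label == cl]
      if (!length(ids)) next
      for (id in sample(ids)) {
        f <- which.min(class_counts[, cl])
        assignments[id] <- f
        class_counts[f, cl] <- class_counts[f, cl] + 1L
      }
    }
  })
  structure(
    list(k = as.integer(k), assignments = assignments, entities = ent,
         mode = "stratified", seed = seed),
    class = "split_plan"
  )
}

#' Split entities into train and validation sets
#'
#' Class-stratified shuffled split at the entity level (both entities of a
#' dual-class patient stay on the same side, to keep patient ids disjoint).
#'
#' @param manifest slide manifest to split.
#' @param frac training fraction (default 0.8).
#' @param seed shuffle seed.
#' @return List of manifests `train` and `val`.
#' @export
split_train_val <- function(manifest, frac = 0.8, seed = 1L) {
  ent <- manifest_entities(manifest)
  n_ent_pat <- table(ent$patient_id)
  dual_pats <- names(n_ent_pat)[n_ent_pat == 2L]
  train_pats <- character(); val_pats <- character()
  with_seed(seed, {
    if (length(dual_pats)) {
      dp <- sample(dual_pats)
      n_tr <- round(frac * length(dp))
      train_pats <- dp[seq_len(n_tr)]
      val_pats <- setdiff(dp, train_pats)
    }
    for (cl in c("control", "tumor")) {
      pats <- unique(ent$patient_id[ent$class_label == cl])
      pats <- setdiff(pats, dual_pats)
      if (!length(pats)) next
      pats <- sample(pats)
      n_tr <- max(1L, min(length(pats) - 1L, round(frac * length(pats))))
      if (length(pats) == 1L) n_tr <- 1L
      train_pats <- c(train_pats, pats[seq_len(n_tr)])
      if (length(pats) > 1L) val_pats <- c(val_pats, pats[-seq_len(n_tr)])
    }
  })
  list(
    train = manifest[manifest$patient_id %in% train_pats, , drop = FALSE],
    val = manifest[manifest$patient_id %in% val_pats, , drop = FALSE]
  )
}

#' Aggregate slide probabilities into a patient-level probability
#'
#' With N > 1 slides for one (patient, class) entity: the componentwise
#' arithmetic mean of the slide probability vectors, passed through
#' softmax. With a single slide, that slide's probabilities are used
#' directly (no softmax), matching the convention that a lone prediction
#' *is* the patient-level prediction.
#'
#' @param slide_probs list of length-2 probability vectors (control, tumor).
#' @param softmax_single also apply softmax when N = 1 (off by default; the
#'   two behaviors genuinely differ, e.g. (0.9, 0.1) would re-map to about
#'   (0.69, 0.31)).
#' @return Length-2 probability vector.
#' @export
aggregate_patient_probability <- function(slide_probs, softmax_single = FALSE) {
  if (length(slide_probs) == 0L) {
    abort_wsimil("no slide probabilities to aggregate", "wsimil_parameter_error")
  }
  m <- do.call(rbind, lapply(slide_probs, as.numeric))
  means <- colMeans(m)
  if (nrow(m) == 1L && !softmax_single) {
    return(as.numeric(m[1L, ]))
  }
  softmax(means)
}

# Rank-based AUC of the tumor-class probability (ties get half credit);
# identical to the Wilcoxon/Mann-Whitney U statistic scaled to [0, 1].
rank_auc <- function(score, truth_tumor) {
  n1 <- sum(truth_tumor); n0 <- sum(!truth_tumor)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth_tumor]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level classification metrics
#'
#' Accuracy and the confusion matrix come from the argmax of the aggregated
#' probabilities (ties resolve to tumor — the conservative call in a
#' screening setting); F1 is the binary F1 with tumor as the positive
#' class; AUC is the tumor-probability rank statistic (pairs correctly
#' ranked, half credit for ties).
#'
#' @param predictions data.frame with columns `patient_id`, `class_label`
#'   (truth), `p_control`, `p_tumor` (and optionally `n_slides`).
#' @return A `metrics_report`: accuracy, f1, auc (NA with a note if only
#'   one class is present), confusion (2 x 2, rows = truth control/tumor),
#'   n_entities.
#' @export
compute_metrics <- function(predictions) {
  stopifnot(all(c("class_label", "p_control", "p_tumor") %in% names(predictions)))
  truth <- factor(predictions$class_label, levels = c("control", "tumor"))
  pred <- factor(
    ifelse(predictions$p_tumor >= predictions$p_control, "tumor", "control"),
    levels = c("control", "tumor")
  )
  confusion <- table(truth = truth, pred = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  tp <- confusion["tumor", "tumor"]; fp <- confusion["control", "tumor"]
  fn <- confusion["tumor", "control"]
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  auc <- rank_auc(predictions$p_tumor, truth == "tumor")
  structure(
    list(accuracy = acc, f1 = f1, auc = auc,
         auc_defined = !is.na(auc),
         confusion = unclass(confusion), n_entities = nrow(predictions)),
    class = "metrics_report"
  )
}

# Slide probabilities -> per-entity predictions data.frame.
entity_predictions <- function(manifest, probs_by_slide) {
  ent <- manifest_entities(manifest)
  rows <- lapply(seq_len(nrow(ent)), function(i) {
    sl <- manifest$slide_id[manifest$patient_id == ent$patient_id[i] &
                              manifest$class_label == ent$class_label[i]]
    p <- aggregate_patient_probability(probs_by_slide[sl])
    data.frame(
      patient_id = ent$patient_id[i], class_label = ent$class_label[i],
      p_control = p[1L], p_tumor = p[2L], n_slides = length(sl),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

assert_no_leakage <- function(train_manifest, test_manifest) {
  common <- intersect(unique(train_manifest$patient_id),
                      unique(test_manifest$patient_id))
  if (length(common)) {
    abort_wsimil(
      paste0("patient-id leakage between train and test: ",
             paste(common, collapse = ", ")),
      "wsimil_leakage_error"
    )
  }
  invisible(TRUE)
}

# Predict every slide of a manifest from cached features.
predict_manifest <- function(params, manifest, cache, backbone, config) {
  store_fn <- manifest_store_fn(manifest)
  probs <- lapply(manifest$slide_id, function(s) {
    feats <- features_for_slide(cache, s, backbone, config, store_fn,
                                variants = "00")
    slide_probs_from_features(params, feats, config,
                              derive_seed(config$seed, "predict", s))
  })
  stats::setNames(probs, manifest$slide_id)
}

pool_manifests <- function(cohorts) {
  m <- do.call(rbind, lapply(cohorts, function(co) co$manifest))
  rownames(m) <- NULL
  m
}

#' Run an evaluation protocol
#'
#' Three protocols over tiled cohorts, all reporting patient-level metrics
#' through the mean-then-softmax aggregation rule:
#' \describe{
#'   \item{`cv`}{patient-wise stratified k-fold cross-validation on one
#'     cohort; each fold's remaining entities are split 80-20 into train
#'     and validation. Reports per-fold metrics and their mean and sd.
#'     With `group_by`, one fold per group value (grouped CV).}
#'   \item{`train_full_test_other`}{train on 80% of the pooled training
#'     cohorts (20% validation), evaluate on a different cohort.}
#'   \item{`train_all_test_holdout`}{identical mechanics with the training
#'     cohorts pooled and a held-out cohort as test; named separately to
#'     mirror the study design (pooling all sources before testing on the
#'     external set).}
#' }
#' Every run asserts that train and test patient ids are disjoint before
#' any model is fit. The frozen backbone and per-slide feature tables are
#' shared across folds of one run.
#'
#' @param train_cohorts a `wsi_cohort` or list of them (pooled for
#'   training).
#' @param config a [model_config()].
#' @param mode one of `"cv"`, `"train_full_test_other"`,
#'   `"train_all_test_holdout"`.
#' @param test_cohort required for the two cross-dataset modes.
#' @param k fold count for `cv`.
#' @param seed protocol seed (folds, splits; model seeds derive from it).
#' @param group_by optional group column for grouped CV.
#' @param feature_cache optional environment of per-slide feature tables,
#'   shared across protocol runs that use the same config seed (and hence
#'   the same frozen backbone) and tile stores.
#' @return A `protocol_result`: list with `mode`, `metrics` (aggregate
#'   `metrics_report`), for cv additionally `per_fold` and
#'   `summary` (mean/sd of accuracy, f1, auc across folds), the fitted
#'   `model` (non-cv modes), and `predictions`.
#' @export
run_protocol <- function(train_cohorts, config,
                         mode = c("cv", "train_full_test_other", "train_all_test_holdout"),
                         test_cohort = NULL, k = 10L, seed = 1L, group_by = NULL,
                         feature_cache = NULL) {
  mode <- match.arg(mode)
  if (inherits(train_cohorts, "wsi_cohort")) train_cohorts <- list(train_cohorts)
  train_manifest <- pool_manifests(train_cohorts)
  check_manifest_integrity(train_manifest)
  backbone <- init_backbone(config)
  cache <- feature_cache %||% new.env(parent = emptyenv())

  fit_and_eval <- function(fit_manifest, test_manifest, fit_seed) {
    assert_no_leakage(fit_manifest, test_manifest)
    tv <- split_train_val(fit_manifest, 0.8, fit_seed)
    assert_no_leakage(tv$train, test_manifest)
    model <- train_model(list(manifest = tv$train), list(manifest = tv$val),
                         config, backbone = backbone, feature_cache = cache)
    probs <- predict_manifest(model$params, test_manifest, cache, backbone, config)
    preds <- entity_predictions(test_manifest, probs)
    list(model = model, predictions = preds, metrics = compute_metrics(preds))
  }

  if (mode == "cv") {
    if (length(train_cohorts) != 1L) {
      abort_wsimil("cv mode expects a single cohort", "wsimil_config_error")
    }
    plan <- make_patient_folds(train_manifest, k = k, seed = seed, group_by = group_by)
    per_fold <- vector("list", plan$k)
    all_preds <- list()
    for (f in seq_len(plan$k)) {
      test_ents <- names(plan$assignments)[plan$assignments == f]
      ent <- plan$entities
      test_pats <- unique(ent$patient_id[ent$entity_id %in% test_ents])
      test_manifest <- train_manifest[train_manifest$patient_id %in% test_pats, , drop = FALSE]
      fit_manifest <- train_manifest[!train_manifest$patient_id %in% test_pats, , drop = FALSE]
      res <- fit_and_eval(fit_manifest, test_manifest, derive_seed(seed, "fold", f))
      per_fold[[f]] <- res$metrics
      all_preds[[f]] <- res$predictions
    }
    vals <- function(what) vapply(per_fold, function(m) m[[what]], numeric(1L))
    summary <- data.frame(
      metric = c("accuracy", "f1", "auc"),
      mean = c(mean(vals("accuracy")), mean(vals("f1")), mean(vals("auc"), na.rm = TRUE)),
      sd = c(stats::sd(vals("accuracy")), stats::sd(vals("f1")),
             stats::sd(vals("auc"), na.rm = TRUE))
    )
    preds <- do.call(rbind, all_preds)
    return(structure(
      list(mode = mode, plan = plan, per_fold = per_fold, summary = summary,
           metrics = compute_metrics(preds), predictions = preds),
      class = "protocol_result"
    ))
  }

  if (is.null(test_cohort)) {
    abort_wsimil("cross-dataset modes require test_cohort", "wsimil_config_error")
  }
  test_manifest <- test_cohort$manifest
  res <- fit_and_eval(train_manifest, test_manifest, derive_seed(seed, mode))
  structure(
    list(mode = mode, metrics = res$metrics, predictions = res$predictions,
         model = res$model),
    class = "protocol_result"
  )
}
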