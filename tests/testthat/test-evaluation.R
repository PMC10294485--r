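# Patient-wise stratified/grouped folds, the mean-then-softmax patient
# aggregation rule, metrics with their brute-force oracles, and leakage
# guards.

fake_manifest <- function(n_control, n_tumor, dataset = "D1", group = NULL) {
  pats <- c(sprintf("%s_C%02d", dataset, seq_len(n_control)),
            sprintf("%s_T%02d", dataset, seq_len(n_tumor)))
  cls <- c(rep("control", n_control), rep("tumor", n_tumor))
  data.frame(
    slide_id = paste0(pats, "_s1"), patient_id = pats, dataset_id = dataset,
    class_label = cls,
    group_label = if (is.null(group)) NA_character_ else rep_len(group, length(pats)),
    store_path = NA_character_, stringsAsFactors = FALSE
  )
}

test_that("stratified folds balance classes within one and never split a patient", {
  m <- fake_manifest(20, 20)
  plan <- make_patient_folds(m, k = 10, seed = 3)
  expect_equal(plan$k, 10L)
  ent <- plan$entities
  for (f in 1:10) {
    in_f <- ent[plan$assignments[ent$entity_id] == f, ]
    expect_equal(sum(in_f$class_label == "control"), 2L)
    expect_equal(sum(in_f$class_label == "tumor"), 2L)
  }

  # a dual-class patient contributes two entities, co-assigned to one fold
  m2 <- rbind(m, data.frame(
    slide_id = "D1_C01_s2", patient_id = "D1_C01", dataset_id = "D1",
    class_label = "tumor", group_label = NA_character_,
    store_path = NA_character_, stringsAsFactors = FALSE
  ))
  plan2 <- make_patient_folds(m2, k = 5, seed = 3)
  f_ctrl <- plan2$assignments[["D1_C01::control"]]
  f_tum <- plan2$assignments[["D1_C01::tumor"]]
  expect_equal(f_ctrl, f_tum)
  # per-fold class counts still within one of perfect stratification
  for (cl in c("control", "tumor")) {
    cnt <- table(factor(
      plan2$assignments[plan2$entities$entity_id[plan2$entities$class_label == cl]],
      levels = 1:5
    ))
    expect_lte(max(cnt) - min(cnt), 1L)
  }

  expect_error(make_patient_folds(fake_manifest(3, 20), k = 10),
               class = "wsimil_config_error")
})

test_that("grouped folds are pure in their group and override k", {
  m <- fake_manifest(6, 6, group = c("pl", "us", "cn"))
  plan <- make_patient_folds(m, k = 99, group_by = "group_label")
  expect_equal(plan$k, 3L)
  for (f in seq_len(plan$k)) {
    ents <- names(plan$assignments)[plan$assignments == f]
    pats <- plan$entities$patient_id[plan$entities$entity_id %in% ents]
    expect_length(unique(m$group_label[m$patient_id %in% pats]), 1L)
  }
})

test_that("patients spanning datasets are a manifest integrity error", {
  m <- rbind(fake_manifest(2, 2, dataset = "D1"),
             fake_manifest(2, 2, dataset = "D2"))
  m$patient_id[nrow(m)] <- m$patient_id[1]  # same patient in both datasets
  m$slide_id[nrow(m)] <- "dup_s9"
  expect_error(make_patient_folds(m, k = 2), class = "wsimil_manifest_error")
})

test_that("train/val splits are patient-disjoint and roughly 80-20", {
  m <- fake_manifest(10, 10)
  tv <- split_train_val(m, 0.8, seed = 5)
  expect_length(intersect(tv$train$patient_id, tv$val$patient_id), 0L)
  expect_equal(nrow(tv$train) + nrow(tv$val), nrow(m))
  expect_equal(nrow(tv$train), 16L)
  expect_setequal(unique(tv$val$class_label), c("control", "tumor"))
})

test_that("patient aggregation follows mean-then-softmax with the single-slide rule", {
  # two slides: means (0.7, 0.3) -> softmax -> (0.5987, 0.4013)
  p <- aggregate_patient_probability(list(c(0.8, 0.2), c(0.6, 0.4)))
  expect_equal(p, c(exp(0.7), exp(0.3)) / (exp(0.7) + exp(0.3)), tolerance = 1e-12)
  expect_equal(p, c(0.5986877, 0.4013123), tolerance = 1e-6)

  # a single slide is used directly, no softmax
  expect_equal(aggregate_patient_probability(list(c(0.9, 0.1))), c(0.9, 0.1))
  # unless explicitly requested
  expect_equal(aggregate_patient_probability(list(c(0.9, 0.1)), softmax_single = TRUE),
               c(exp(0.9), exp(0.1)) / (exp(0.9) + exp(0.1)))

  # symmetry fixed point
  expect_equal(aggregate_patient_probability(list(c(0.5, 0.5), c(0.5, 0.5))),
               c(0.5, 0.5))
  expect_error(aggregate_patient_probability(list()), class = "wsimil_parameter_error")
})

test_that("aggregation matches an independent mean+softmax oracle on random input", {
  oracle <- function(lst) {
    mat <- matrix(unlist(lst), ncol = 2, byrow = TRUE)
    if (nrow(mat) == 1) return(mat[1, ])
    mu <- c(mean(mat[, 1]), mean(mat[, 2]))
    exp(mu) / sum(exp(mu))
  }
  wsimil:::with_seed(99, {
    for (i in 1:200) {
      n <- sample(1:6, 1)
      lst <- lapply(seq_len(n), function(j) {
        a <- runif(1)
        c(a, 1 - a)
      })
      expect_equal(aggregate_patient_probability(lst), oracle(lst), tolerance = 1e-9)
    }
  })
})

test_that("metrics: accuracy, F1, confusion and rank AUC with its pair oracle", {
  perfect <- data.frame(
    patient_id = letters[1:4], class_label = c("control", "control", "tumor", "tumor"),
    p_control = c(0.9, 0.8, 0.1, 0.2), p_tumor = c(0.1, 0.2, 0.9, 0.8)
  )
  mp <- compute_metrics(perfect)
  expect_equal(mp$accuracy, 1); expect_equal(mp$f1, 1); expect_equal(mp$auc, 1)

  # confusion [[3,1],[2,4]] rows truth control/tumor -> accuracy 0.7
  truth <- c(rep("control", 4), rep("tumor", 6))
  pred_tumor <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.9)
  df <- data.frame(patient_id = paste0("p", 1:10), class_label = truth,
                   p_control = 1 - pred_tumor, p_tumor = pred_tumor)
  mm <- compute_metrics(df)
  expect_equal(unname(mm$confusion), matrix(c(3, 2, 1, 4), 2), ignore_attr = TRUE)
  expect_equal(mm$accuracy, 0.7)

  # AUC = fraction of (tumor, control) pairs ranked correctly, half credit ties
  pair_auc <- function(score, is_tumor) {
    s1 <- score[is_tumor]; s0 <- score[!is_tumor]
    tot <- 0
    for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(s1) * length(s0))
  }
  wsimil:::with_seed(7, {
    for (i in 1:20) {
      sc <- round(runif(12), 1)  # rounding forces ties
      tum <- sample(c(TRUE, FALSE), 12, replace = TRUE)
      if (!any(tum) || all(tum)) next
      d <- data.frame(patient_id = paste0("q", 1:12),
                      class_label = ifelse(tum, "tumor", "control"),
                      p_control = 1 - sc, p_tumor = sc)
      expect_equal(compute_metrics(d)$auc, pair_auc(sc, tum), tolerance = 1e-12)
    }
  })

  # argmax ties resolve toward tumor
  tie <- data.frame(patient_id = "t", class_label = "tumor",
                    p_control = 0.5, p_tumor = 0.5)
  expect_equal(compute_metrics(tie)$accuracy, 1)

  # single-class input: AUC undefined, the rest computed
  one <- df[df$class_label == "tumor", ]
  mo <- compute_metrics(one)
  expect_false(mo$auc_defined)
  expect_true(is.finite(mo$accuracy))
})

test_that("metric bounds and confusion conservation hold on random predictions", {
  wsimil:::with_seed(31, {
    for (i in 1:20) {
      n <- sample(4:30, 1)
      p <- runif(n)
      d <- data.frame(patient_id = paste0("r", 1:n),
                      class_label = sample(c("control", "tumor"), n, replace = TRUE),
                      p_control = 1 - p, p_tumor = p)
      m <- compute_metrics(d)
      expect_equal(sum(m$confusion), n)
      expect_gte(m$accuracy, 0); expect_lte(m$accuracy, 1)
      if (m$auc_defined) { expect_gte(m$auc, 0); expect_lte(m$auc, 1) }
      expect_equal(m$accuracy, sum(diag(m$confusion)) / n)
    }
  })
})

test_that("leakage between train and test manifests is a hard error", {
  m <- fake_manifest(4, 4)
  expect_error(wsimil:::assert_no_leakage(m[1:4, ], m[c(5:8, 1), ]),
               class = "wsimil_leakage_error")
  expect_silent(wsimil:::assert_no_leakage(m[1:4, ], m[5:8, ]))
})

test_that("grouped-CV protocol builds one leakage-free fold per group", {
  spec <- cohort_spec(
    datasets = data.frame(dataset_id = "G1", n_control = 6, n_tumor = 6),
    slide_size = c(512L, 512L), tissue_fraction = 0.85,
    groups = c("pl", "us", "cn"), seed = 47L
  )
  co <- tile_cohort(generate_cohort(spec), file.path(tempdir(), "wsimil_grp"),
                    seed = 47L)
  cfg <- model_config(bag_size = 4L, tiles_per_slide = 8L, batch_size = 4L,
                      max_epochs = 6L, patience = 3L, seed = 47L)
  res <- run_protocol(co, cfg, mode = "cv", seed = 47L, group_by = "group_label")
  expect_equal(res$plan$k, 3L)
  expect_length(res$per_fold, 3L)
  # every tested entity's group matches its fold's group
  for (f in seq_len(res$plan$k)) {
    ents <- names(res$plan$assignments)[res$plan$assignments == f]
    pats <- res$plan$entities$patient_id[res$plan$entities$entity_id %in% ents]
    grp <- unique(co$manifest$group_label[co$manifest$patient_id %in% pats])
    expect_equal(grp, res$plan$groups[f])
  }
  expect_equal(res$metrics$n_entities, 12L)
})
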