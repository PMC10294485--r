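#' Specify a synthetic multi-center slide cohort
#'
#' A cohort specification fixes everything the generator needs to produce a
#' reproducible set of synthetic H&E-like slides: how many patients of each
#' class each dataset contributes, the slide geometry, the class-specific
#' texture signal (dark nuclei-like spots on a pink tissue base), and the
#' dataset-specific stain cast applied to tissue pixels.
#'
#' @param datasets data.frame with columns `dataset_id`, `n_control`,
#'   `n_tumor` (patient counts per class; a patient's class here is its
#'   *primary* class, see `dual_class_patient_rate`).
#' @param slide_size integer length-2, slide height and width in pixels.
#' @param tissue_fraction fraction of the slide area covered by the
#'   contiguous tissue region, in (0, 1]. Values >= 0.99 produce an
#'   all-tissue slide with a thin background strip so the grayscale
#'   histogram stays bimodal.
#' @param texture_params list with elements `control` and `tumor`, each a
#'   list `list(density = spots per 1e4 px^2 of tissue, radius = spot radius
#'   in px)`.
#' @param tumor_purity fraction of a tumor slide's tissue area carrying
#'   tumor texture; the remainder keeps control texture, emulating the
#'   normal tissue found inside real tumor sections.
#' @param stain_cast named list (one entry per dataset_id) describing the
#'   dataset's presentation fingerprint:
#'   `list(mult = <3 floats>, add = <3 numbers>, spot_gain = <float>,
#'   density_gain = <float>)`. `mult`/`add` are applied to tissue pixels
#'   only as `pixel * mult + add`, clipped to \[0, 255\] (a global color
#'   shift — the kind of variation stain normalization removes);
#'   `spot_gain` (default 1) scales the darkness of the nuclei-like spots
#'   relative to the tissue base (lab-specific hematoxylin intensity);
#'   `density_gain` (default 1) scales the apparent cellularity — the
#'   absolute spot density of both classes — emulating differences in
#'   tissue source and preparation (e.g. surgical resections vs. autopsy
#'   material), a spatial-structure difference that per-tile color
#'   normalization cannot remove.
#' @param slides_per_patient integer, slides of the primary class per patient.
#' @param dual_class_patient_rate fraction of a dataset's patients that
#'   additionally receive one slide of the opposite class. Requires the
#'   dataset to provide both classes.
#' @param groups optional character vector of group labels (e.g. country
#'   codes) cycled over patients, or NULL.
#' @param seed integer master seed; fixes the cohort bit-for-bit.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(datasets,
                        slide_size = c(1024L, 1024L),
                        tissue_fraction = 0.75,
                        texture_params = list(
                          control = list(density = 3, radius = 4),
                          tumor = list(density = 6, radius = 6)
                        ),
                        tumor_purity = 0.8,
                        stain_cast = NULL,
                        slides_per_patient = 1L,
                        dual_class_patient_rate = 0,
                        groups = NULL,
                        seed = 1L) {
  datasets <- as.data.frame(datasets, stringsAsFactors = FALSE)
  stopifnot(
    all(c("dataset_id", "n_control", "n_tumor") %in% names(datasets)),
    all(datasets$n_control >= 0), all(datasets$n_tumor >= 0),
    length(slide_size) == 2L, all(slide_size >= 256L)
  )
  if (!(tissue_fraction > 0 && tissue_fraction <= 1)) {
    abort_wsimil("tissue_fraction must lie in (0, 1]", "wsimil_parameter_error")
  }
  for (cl in c("control", "tumor")) {
    tp <- texture_params[[cl]]
    if (is.null(tp) || tp$density < 0 || tp$radius <= 0) {
      abort_wsimil("texture_params needs non-negative density and positive radius per class",
                   "wsimil_parameter_error")
    }
    if (tp$radius >= min(slide_size) / 4) {
      abort_wsimil("spot radius must be below min(slide_size)/4", "wsimil_parameter_error")
    }
  }
  if (dual_class_patient_rate < 0 || dual_class_patient_rate > 1) {
    abort_wsimil("dual_class_patient_rate must lie in [0, 1]", "wsimil_parameter_error")
  }
  if (is.null(stain_cast)) {
    stain_cast <- stats::setNames(
      rep(list(list(mult = c(1, 1, 1), add = c(0, 0, 0))), nrow(datasets)),
      datasets$dataset_id
    )
  }
  missing_cast <- setdiff(datasets$dataset_id, names(stain_cast))
  if (length(missing_cast)) {
    abort_wsimil(paste0("stain_cast missing for dataset: ", paste(missing_cast, collapse = ", ")),
                 "wsimil_parameter_error")
  }
  stain_cast <- lapply(stain_cast, function(cc) {
    cc$spot_gain <- cc$spot_gain %||% 1
    cc$density_gain <- cc$density_gain %||% 1
    cc$radius_gain <- cc$radius_gain %||% 1
    if (cc$spot_gain <= 0 || cc$density_gain <= 0 || cc$radius_gain <= 0) {
      abort_wsimil("spot_gain, density_gain and radius_gain must be positive",
                   "wsimil_parameter_error")
    }
    cc
  })
  structure(
    list(
      datasets = datasets,
      slide_size = as.integer(slide_size),
      tissue_fraction = tissue_fraction,
      texture_params = texture_params,
      tumor_purity = tumor_purity,
      stain_cast = stain_cast,
      slides_per_patient = as.integer(slides_per_patient),
      dual_class_patient_rate = dual_class_patient_rate,
      groups = groups,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Elliptical tissue region of approximately the requested area fraction.
# Fractions >= 0.99 yield all-tissue minus a background strip (1/8 of the
# rows) at the top: enough background weight that the dominant
# between-class-variance split of the gray histogram stays at the
# background/tissue boundary, which is the premise Otsu masking relies on.
tissue_region <- function(H, W, fraction) {
  if (fraction >= 0.99) {
    m <- matrix(TRUE, H, W)
    m[seq_len(max(16L, H %/% 8L)), ] <- FALSE
    return(m)
  }
  scale <- sqrt(fraction * 4 / pi)
  a <- scale * H / 2
  b <- scale * W / 2
  r <- (seq_len(H) - (H + 1) / 2) / a
  c_ <- (seq_len(W) - (W + 1) / 2) / b
  outer(r^2, c_^2, `+`) <= 1
}

# Rasterize n dark elliptical spots with centers uniform over `region`.
# Radii jitter by +/-25% per axis. Returns a logical mask.
rasterize_spots <- function(H, W, region, n, radius) {
  mask <- matrix(FALSE, H, W)
  if (n <= 0L || !any(region)) return(mask)
  centers <- sample(which(region), n, replace = TRUE)
  rows <- ((centers - 1L) %% H) + 1L
  cols <- ((centers - 1L) %/% H) + 1L
  rx <- radius * stats::runif(n, 0.75, 1.25)
  ry <- radius * stats::runif(n, 0.75, 1.25)
  for (i in seq_len(n)) {
    r0 <- max(1L, floor(rows[i] - rx[i])); r1 <- min(H, ceiling(rows[i] + rx[i]))
    c0 <- max(1L, floor(cols[i] - ry[i])); c1 <- min(W, ceiling(cols[i] + ry[i]))
    dr <- (r0:r1 - rows[i]) / rx[i]
    dc <- (c0:c1 - cols[i]) / ry[i]
    inside <- outer(dr^2, dc^2, `+`) <= 1
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | inside
  }
  mask & region
}

#' Generate one synthetic H&E-like slide
#'
#' Produces a slide with a near-white background (gray ~ N(242, 4)), a
#' contiguous pink tissue region covering about `tissue_fraction` of the
#' area, class-dependent dark nuclei-like spots (tumor slides carry denser,
#' larger spots over `tumor_purity` of the tissue; the rest keeps control
#' texture), and the dataset's stain cast applied to tissue pixels only.
#' Deterministic: the same `seed` yields a byte-identical slide.
#'
#' @param patient_id,class_label,dataset_id identity of the slide;
#'   `class_label` must be "control" or "tumor".
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this slide.
#' @param slide_id optional slide identifier (defaults to `<patient>_s1`).
#' @param group_label optional group label carried into the record.
#' @return A `slide_record`: list with `slide_id`, `patient_id`,
#'   `dataset_id`, `class_label`, `group_label`, `image` (H x W x 3 integer
#'   array in \[0, 255\]), `tissue_mask` and `spot_mask` (logical matrices;
#'   the generator's own ground truth, useful for validating masking).
#' @export
generate_slide <- function(patient_id, class_label, dataset_id, spec, seed,
                           slide_id = paste0(patient_id, "_s1"),
                           group_label = NA_character_) {
  if (!inherits(spec, "cohort_spec")) {
    abort_wsimil("spec must be a cohort_spec", "wsimil_parameter_error")
  }
  if (!class_label %in% c("control", "tumor")) {
    abort_wsimil(paste0("unknown class_label: ", class_label), "wsimil_parameter_error")
  }
  if (!dataset_id %in% spec$datasets$dataset_id) {
    abort_wsimil(paste0("unknown dataset_id: ", dataset_id), "wsimil_parameter_error")
  }
  H <- spec$slide_size[1L]; W <- spec$slide_size[2L]
  cast <- spec$stain_cast[[dataset_id]]
  with_seed(seed, {
    tissue <- tissue_region(H, W, spec$tissue_fraction)
    # background: near-white gray, shared across channels
    bg_idx <- which(!tissue)
    ti_idx <- which(tissue)
    g_bg <- 242 + stats::rnorm(length(bg_idx), 0, 4)
    planes <- vector("list", 3L)

    # pink/purple tissue base
    base_col <- c(205, 158, 188)
    nt <- length(ti_idx)
    for (ch in 1:3) {
      plane <- numeric(H * W)
      plane[bg_idx] <- g_bg
      plane[ti_idx] <- base_col[ch] + stats::rnorm(nt, 0, 9)
      planes[[ch]] <- plane
    }

    # class-dependent spot texture; tumor slides keep control texture on a
    # (1 - tumor_purity) band of tissue columns, emulating admixed normal tissue
    tp_c <- spec$texture_params$control
    tp_t <- spec$texture_params$tumor
    if (class_label == "tumor" && spec$tumor_purity < 1) {
      tis_cols <- which(colSums(tissue) > 0)
      cutoff <- stats::quantile(tis_cols, 1 - spec$tumor_purity, names = FALSE, type = 1)
      colidx <- matrix(rep(seq_len(W), each = H), H, W)
      ctrl_region <- tissue & colidx <= cutoff
      tum_region <- tissue & !ctrl_region
    } else if (class_label == "tumor") {
      ctrl_region <- tissue & FALSE
      tum_region <- tissue
    } else {
      ctrl_region <- tissue
      tum_region <- tissue & FALSE
    }
    dgain <- cast$density_gain %||% 1
    rgain <- cast$radius_gain %||% 1
    n_ctrl <- round(dgain * tp_c$density * sum(ctrl_region) / 1e4)
    n_tum <- round(dgain * tp_t$density * sum(tum_region) / 1e4)
    spot_mask <- rasterize_spots(H, W, ctrl_region, n_ctrl, rgain * tp_c$radius) |
      rasterize_spots(H, W, tum_region, n_tum, rgain * tp_t$radius)

    # moderately dark purple: the class signal is spot *density*, and the
    # spot mode must stay closer to the tissue base than the tissue base is
    # to the background, so the slide histogram's dominant split remains
    # background-vs-tissue (the Otsu premise). The dataset's spot_gain
    # scales the spot/base contrast (hematoxylin intensity).
    gain <- cast$spot_gain %||% 1
    spot_col <- base_col + gain * (c(150, 105, 160) - base_col)
    sp_idx <- which(spot_mask)
    ns <- length(sp_idx)
    img_i <- array(0L, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- planes[[ch]]
      if (ns > 0) plane[sp_idx] <- spot_col[ch] + stats::rnorm(ns, 0, 6)
      # dataset stain cast on tissue pixels only
      plane[ti_idx] <- plane[ti_idx] * cast$mult[ch] + cast$add[ch]
      plane <- round(plane)
      plane[plane < 0] <- 0
      plane[plane > 255] <- 255
      img_i[, , ch] <- as.integer(plane)
    }

    structure(
      list(
        slide_id = slide_id,
        patient_id = patient_id,
        dataset_id = dataset_id,
        class_label = class_label,
        group_label = group_label,
        image = img_i,
        tissue_mask = tissue,
        spot_mask = spot_mask
      ),
      class = "slide_record"
    )
  })
}

#' Generate a cohort manifest (and optionally its slides)
#'
#' Builds the slide manifest implied by a [cohort_spec()]: every patient
#' contributes `slides_per_patient` slides of its primary class, and
#' `dual_class_patient_rate` of the patients additionally receive one slide
#' of the opposite class (these are the "dual-class" patients that the
#' evaluation module treats as two independent (patient, class) entities).
#' Slides themselves are regenerated on demand from the manifest via
#' [cohort_slide()], so large cohorts never need to be held in memory.
#'
#' @param spec a [cohort_spec()].
#' @param materialize if TRUE, also generate every slide and return it in
#'   `$slides` (only sensible for small cohorts).
#' @return A `wsi_cohort`: list with `spec`, `manifest` (data.frame with
#'   columns slide_id, patient_id, dataset_id, class_label, group_label,
#'   slide_seed, store_path) and optionally `slides`.
#' @export
generate_cohort <- function(spec, materialize = FALSE) {
  rows <- list()
  for (d in seq_len(nrow(spec$datasets))) {
    ds <- spec$datasets$dataset_id[d]
    n_c <- spec$datasets$n_control[d]
    n_t <- spec$datasets$n_tumor[d]
    pats_c <- if (n_c > 0) sprintf("%s_C%03d", ds, seq_len(n_c)) else character()
    pats_t <- if (n_t > 0) sprintf("%s_T%03d", ds, seq_len(n_t)) else character()
    n_pat <- n_c + n_t
    n_dual <- round(spec$dual_class_patient_rate * n_pat)
    if (n_dual > 0 && (n_c == 0 || n_t == 0)) {
      abort_wsimil(
        paste0("dual-class patients requested in single-class dataset ", ds),
        "wsimil_parameter_error"
      )
    }
    dual_c <- dual_t <- character()
    if (n_dual > 0) {
      kc <- min(n_c, ceiling(n_dual / 2))
      kt <- min(n_t, n_dual - kc)
      kc <- min(n_c, n_dual - kt)  # top up from controls if tumors ran short
      with_seed(derive_seed(spec$seed, ds, "dual"), {
        dual_c <- sample(pats_c, kc)
        dual_t <- sample(pats_t, kt)
      })
    }
    pats <- c(pats_c, pats_t)
    primary <- c(rep("control", n_c), rep("tumor", n_t))
    grp <- if (is.null(spec$groups)) {
      rep(NA_character_, n_pat)
    } else {
      rep_len(spec$groups, n_pat)
    }
    for (i in seq_along(pats)) {
      p <- pats[i]
      n_slides <- spec$slides_per_patient
      classes <- rep(primary[i], n_slides)
      if (p %in% c(dual_c, dual_t)) {
        classes <- c(classes, setdiff(c("control", "tumor"), primary[i]))
      }
      for (k in seq_along(classes)) {
        sid <- sprintf("%s_s%d", p, k)
        rows[[length(rows) + 1L]] <- data.frame(
          slide_id = sid, patient_id = p, dataset_id = ds,
          class_label = classes[k], group_label = grp[i],
          slide_seed = derive_seed(spec$seed, sid),
          store_path = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  cohort <- structure(list(spec = spec, manifest = manifest), class = "wsi_cohort")
  if (materialize) {
    cohort$slides <- stats::setNames(
      lapply(seq_len(nrow(manifest)), function(i) cohort_slide(cohort, manifest$slide_id[i])),
      manifest$slide_id
    )
  }
  cohort
}

#' Materialize one slide of a cohort from its manifest row
#'
#' @param cohort a `wsi_cohort` from [generate_cohort()].
#' @param slide_id the slide to generate.
#' @return A `slide_record` (identical across calls: generation is seeded
#'   per slide).
#' @export
cohort_slide <- function(cohort, slide_id) {
  row <- cohort$manifest[cohort$manifest$slide_id == slide_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    abort_wsimil(paste0("unknown slide_id: ", slide_id), "wsimil_parameter_error")
  }
  generate_slide(
    patient_id = row$patient_id, class_label = row$class_label,
    dataset_id = row$dataset_id, spec = cohort$spec, seed = row$slide_seed,
    slide_id = row$slide_id, group_label = row$group_label
  )
}

#' Build the confounded multi-center scenario
#'
#' Emulates the structure of a multi-center study in which one source
#' contributes almost only tumor slides (cohort A), one only control slides
#' (cohort B), one both classes (cohort C), and a small balanced held-out
#' set (cohort T). A and B carry opposing stain casts, so in A+B the class
#' label is almost perfectly predictable from color alone; C and T carry
#' their own milder casts. Patient-id namespaces of the four cohorts are
#' disjoint.
#'
#' @param preset currently only `"confounded_trio"`.
#' @param scale integer factor multiplying the A/B patient counts
#'   (C and T stay fixed at 12+12 and 5+5).
#' @param seed master seed; each cohort derives its own seed from it.
#' @param stain_casts if FALSE, all casts are identity (the "confounding
#'   knob" turned off; color then carries no dataset signal).
#' @return Named list of `wsi_cohort`s: A, B, C, T.
#' @export
make_multicenter_scenario <- function(preset = "confounded_trio", scale = 1L,
                                      seed = 1L, stain_casts = TRUE) {
  if (!identical(preset, "confounded_trio")) {
    abort_wsimil(paste0("unknown preset: ", preset), "wsimil_parameter_error")
  }
  idcast <- list(mult = c(1, 1, 1), add = c(0, 0, 0),
                 spot_gain = 1, density_gain = 1, radius_gain = 1)
  casts <- list(
    A = list(mult = c(1.12, 0.92, 0.88), add = c(6, -4, -8),
             spot_gain = 1.15, density_gain = 1.6, radius_gain = 1.15),
    B = list(mult = c(0.88, 0.94, 1.12), add = c(-8, 0, 8),
             spot_gain = 0.80, density_gain = 0.7, radius_gain = 0.80),
    C = list(mult = c(0.97, 1.00, 1.05), add = c(0, 0, 3),
             spot_gain = 0.90, density_gain = 0.8, radius_gain = 0.80),
    T = list(mult = c(0.99, 1.00, 1.02), add = c(1, 0, 1),
             spot_gain = 0.92, density_gain = 0.8, radius_gain = 0.80)
  )
  if (!stain_casts) casts <- lapply(casts, function(x) idcast)
  mk <- function(ds, n_c, n_t, dual_rate, groups) {
    cohort_spec(
      datasets = data.frame(dataset_id = ds, n_control = n_c, n_tumor = n_t),
      stain_cast = stats::setNames(list(casts[[ds]]), ds),
      dual_class_patient_rate = dual_rate,
      groups = groups,
      seed = derive_seed(seed, ds)
    )
  }
  specs <- list(
    A = mk("A", 2L * scale, 20L * scale, 0, c("us", "ca")),
    B = mk("B", 20L * scale, 0L, 0, c("us", "de")),
    C = mk("C", 12L, 12L, 1 / 6, c("us", "pl", "cn")),
    T = mk("T", 5L, 5L, 0, "es")
  )
  lapply(specs, generate_cohort)
}

#' Write a cohort manifest as tab-separated text
#'
#' The manifest TSV is the single handoff format between the generator, the
#' tiler and the evaluation protocols.
#'
#' @param cohort a `wsi_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.table(cohort$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest written by [write_manifest()]
#' @param path manifest TSV path.
#' @return data.frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
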