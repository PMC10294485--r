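#' Otsu threshold of a grayscale sample
#'
#' Exhaustive-equivalent Otsu: builds the 256-bin histogram of the (floored)
#' gray values and returns the cut point `t` maximizing the between-class
#' variance of the split `gray < t` vs `gray >= t`. Ties resolve to the
#' lowest threshold.
#'
#' @param gray numeric matrix/vector of gray levels in \[0, 255\].
#' @return integer threshold in 1..255.
#' @export
otsu_threshold <- function(gray) {
  v <- floor(as.numeric(gray))
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  # cut t means class0 = bins 0..t-1, class1 = bins t..255
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * levels)
  mu_t <- mu[256L]
  mu0_num <- mu[1:255]
  w1 <- 1 - w0
  between <- ifelse(
    w0 > 0 & w1 > 0,
    (mu_t * w0 - mu0_num)^2 / (w0 * w1),
    -Inf
  )
  which.max(between)  # threshold t (class boundary between bins t-1 and t)
}

#' Compute the tissue mask of a slide
#'
#' Converts the slide to luma grayscale, finds the Otsu threshold of the
#' 256-bin histogram, and marks the darker side as tissue (H&E tissue is
#' darker than the near-white scanner background).
#'
#' @param slide a `slide_record` (or any list with `$image` and `$slide_id`).
#' @return A `tissue_mask`: list with `mask` (logical H x W, TRUE = tissue)
#'   and `otsu_threshold` (gray level).
#' @export
compute_tissue_mask <- function(slide) {
  img <- slide$image
  gray <- to_gray(img)
  if (max(gray) - min(gray) < 1) {
    abort_wsimil(
      paste0("degenerate grayscale histogram (constant image) for slide ",
             slide$slide_id %||% "<unnamed>"),
      "wsimil_degenerate_histogram"
    )
  }
  thr <- otsu_threshold(gray)
  structure(
    list(mask = gray < thr, otsu_threshold = thr, slide_id = slide$slide_id),
    class = "tissue_mask"
  )
}

#' Select tiles from per-tile filter statistics
#'
#' The pure filtering/capping rule, separated from pixel handling so it can
#' be exercised at manifest scale: a tile is kept iff its background
#' fraction is at most `bg_max` (strictly more than `bg_max` background is
#' discarded) and its grayscale standard deviation is at least
#' `contrast_min`; if more than `max_tiles` survive, a uniform random
#' subsample of exactly `max_tiles` is drawn. Subsampling operates on the
#' lexicographically sorted tile ids, so the kept set is independent of the
#' row order of `stats`.
#'
#' @param stats data.frame with columns `tile_id`, `background_fraction`,
#'   `contrast_stat`.
#' @param bg_max maximum tolerated background fraction (default 0.60).
#' @param contrast_min minimum grayscale standard deviation (default 8).
#' @param max_tiles cap on kept tiles (default 4000).
#' @param seed seed for the cap subsample.
#' @return Character vector of kept tile ids (sorted).
#' @export
select_tiles <- function(stats, bg_max = 0.60, contrast_min = 8,
                         max_tiles = 4000L, seed = 1L) {
  keep <- stats$background_fraction <= bg_max & stats$contrast_stat >= contrast_min
  ids <- sort(stats$tile_id[keep])
  if (length(ids) > max_tiles) {
    ids <- sort(with_seed(seed, sample(ids, max_tiles)))
  }
  ids
}

#' Extract filtered fixed-size tiles from a slide
#'
#' Places a non-overlapping `tile_size` grid anchored at pixel (0, 0)
#' (partial edge tiles are dropped), computes per-tile background fraction
#' (from the slide-level tissue mask restricted to the tile footprint) and
#' grayscale standard deviation, and keeps tiles via [select_tiles()].
#'
#' @param slide a `slide_record`.
#' @param mask a `tissue_mask` from [compute_tissue_mask()].
#' @param tile_size tile edge length in pixels (default 256).
#' @param bg_max,contrast_min,max_tiles,seed filtering parameters, see
#'   [select_tiles()]. The cap subsample seed is derived from `seed` and the
#'   slide id.
#' @return A `tile_store`: list with `slide_id`, `tiles` (n x ts x ts x 3
#'   integer array), `tile_ids`, `origins` (n x 2, 0-based top-left row/col),
#'   `background_fraction`, `contrast_stat`, `n_candidates`, `n_kept`,
#'   `extraction_seed`, `undersized` flag. A slide smaller than `tile_size`
#'   yields an empty store with `undersized = TRUE` and a warning.
#' @export
extract_tiles <- function(slide, mask, tile_size = 256L, bg_max = 0.60,
                          contrast_min = 8, max_tiles = 4000L, seed = 1L) {
  img <- slide$image
  H <- dim(img)[1L]; W <- dim(img)[2L]
  ts <- as.integer(tile_size)
  nr <- H %/% ts; nc <- W %/% ts
  ex_seed <- derive_seed(seed, slide$slide_id %||% "slide")
  empty_store <- function(n_cand, undersized) {
    structure(
      list(
        slide_id = slide$slide_id,
        tiles = array(integer(), dim = c(0L, ts, ts, 3L)),
        tile_ids = character(), origins = matrix(integer(), 0L, 2L),
        background_fraction = numeric(), contrast_stat = numeric(),
        n_candidates = n_cand, n_kept = 0L,
        extraction_seed = ex_seed, undersized = undersized
      ),
      class = "tile_store"
    )
  }
  if (nr < 1L || nc < 1L) {
    warning("slide ", slide$slide_id, " smaller than tile_size; empty store")
    return(empty_store(0L, TRUE))
  }
  gray <- to_gray(img)
  grid <- expand.grid(r = seq_len(nr) - 1L, c = seq_len(nc) - 1L)
  n_cand <- nrow(grid)
  stats_df <- data.frame(
    tile_id = sprintf("%s_t%03d_%03d", slide$slide_id, grid$r, grid$c),
    row0 = grid$r * ts, col0 = grid$c * ts,
    background_fraction = NA_real_, contrast_stat = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_cand)) {
    rr <- stats_df$row0[i] + seq_len(ts)
    cc <- stats_df$col0[i] + seq_len(ts)
    stats_df$background_fraction[i] <- mean(!mask$mask[rr, cc])
    stats_df$contrast_stat[i] <- stats::sd(gray[rr, cc])
  }
  kept_ids <- select_tiles(stats_df, bg_max, contrast_min, max_tiles, ex_seed)
  kept <- stats_df[match(kept_ids, stats_df$tile_id), , drop = FALSE]
  n_kept <- nrow(kept)
  if (n_kept == 0L) return(empty_store(n_cand, FALSE))
  tiles <- array(0L, dim = c(n_kept, ts, ts, 3L))
  for (i in seq_len(n_kept)) {
    rr <- kept$row0[i] + seq_len(ts)
    cc <- kept$col0[i] + seq_len(ts)
    tiles[i, , , ] <- img[rr, cc, ]
  }
  structure(
    list(
      slide_id = slide$slide_id,
      tiles = tiles,
      tile_ids = kept$tile_id,
      origins = cbind(row = kept$row0, col = kept$col0),
      background_fraction = kept$background_fraction,
      contrast_stat = kept$contrast_stat,
      n_candidates = n_cand, n_kept = n_kept,
      extraction_seed = ex_seed, undersized = FALSE
    ),
    class = "tile_store"
  )
}

# Pull one tile (ts x ts x 3 integer array) out of a store.
store_tile <- function(store, i) {
  array(store$tiles[i, , , ], dim = dim(store$tiles)[2:4])
}

tile_store_members <- c(
  "slide_id", "tiles", "tile_ids", "origins", "background_fraction",
  "contrast_stat", "n_candidates", "n_kept", "extraction_seed", "undersized"
)

#' Write a tile store to disk
#'
#' Serializes the store as a hierarchical array container holding the
#' `tiles` array (n x ts x ts x 3, 8-bit range), parallel `origins`,
#' `background_fraction` and `contrast_stat` arrays, and the scalar
#' attributes. Round trips are lossless.
#'
#' @param store a `tile_store`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tile_store <- function(store, path) {
  stopifnot(inherits(store, "tile_store"))
  saveRDS(unclass(store)[tile_store_members], path)
  invisible(path)
}

#' Read a tile store written by [write_tile_store()]
#'
#' Validates the container layout and fails with a format error naming the
#' missing or malformed member.
#'
#' @param path file path.
#' @return A `tile_store`.
#' @export
read_tile_store <- function(path) {
  if (!file.exists(path)) {
    abort_wsimil(paste0("tile store file not found: ", path), "wsimil_format_error")
  }
  obj <- readRDS(path)
  missing <- setdiff(tile_store_members, names(obj))
  if (length(missing)) {
    abort_wsimil(paste0("tile store missing member(s): ", paste(missing, collapse = ", ")),
                 "wsimil_format_error")
  }
  dt <- dim(obj$tiles)
  if (length(dt) != 4L || dt[4L] != 3L || dt[2L] != dt[3L]) {
    abort_wsimil("tile store member 'tiles' must have shape (n, ts, ts, 3)",
                 "wsimil_format_error")
  }
  if (dt[1L] != obj$n_kept || nrow(obj$origins) != obj$n_kept ||
      length(obj$background_fraction) != obj$n_kept ||
      length(obj$contrast_stat) != obj$n_kept) {
    abort_wsimil("tile store member lengths disagree with n_kept",
                 "wsimil_format_error")
  }
  structure(obj, class = "tile_store")
}

#' Tile every slide of a cohort, streaming to disk
#'
#' Regenerates each slide from the cohort manifest, computes its tissue
#' mask, extracts filtered tiles and writes one tile-store file per slide
#' under `dir`. Slides are processed one at a time, so memory stays bounded
#' regardless of cohort size.
#'
#' @param cohort a `wsi_cohort`.
#' @param dir output directory (created if needed).
#' @param ... passed to [extract_tiles()] (`bg_max`, `contrast_min`,
#'   `max_tiles`, `seed`, `tile_size`).
#' @return The cohort with `manifest$store_path` filled in.
#' @export
tile_cohort <- function(cohort, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    slide <- cohort_slide(cohort, m$slide_id[i])
    mask <- compute_tissue_mask(slide)
    store <- extract_tiles(slide, mask, ...)
    path <- file.path(dir, paste0(m$slide_id[i], ".tiles.rds"))
    write_tile_store(store, path)
    m$store_path[i] <- path
  }
  cohort$manifest <- m
  cohort
}
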