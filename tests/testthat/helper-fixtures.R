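# Shared fixtures. Everything is generated in code at test time; the
# expensive multi-center scenario is tiled once per seed and memoized for
# the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

# A small two-class single-dataset spec on 512x512 slides (2x2 tile grid),
# fast enough for contract-level tests.
small_spec <- function(n_control = 4L, n_tumor = 4L, seed = 11L, ...) {
  cohort_spec(
    datasets = data.frame(dataset_id = "D1", n_control = n_control, n_tumor = n_tumor),
    slide_size = c(512L, 512L), tissue_fraction = 0.85,
    seed = seed, ...
  )
}

# Tiled version of the small cohort (memoized).
small_tiled_cohort <- function(seed = 11L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]])) {
    co <- generate_cohort(small_spec(seed = seed))
    dir <- file.path(tempdir(), paste0("wsimil_small_", seed))
    .fixture_cache[[key]] <- tile_cohort(co, dir, seed = seed)
  }
  .fixture_cache[[key]]
}

# Desk-scale training configuration used throughout the synthetic
# experiments: 16-tile slides give 2 bags of 8 per slide (mirroring the
# 2-bags-per-slide full-scale recipe), one bag per optimizer step, with
# Reinhard stain normalization on (as the full-scale recipe trains).
desk_config <- function(seed, ...) {
  model_config(
    bag_size = 8L, tiles_per_slide = 16L, batch_size = 8L,
    max_epochs = 40L, patience = 10L, seed = seed,
    normalizer = reinhard_preset(), ...
  )
}

# Tiled confounded multi-center scenario plus the desk-scale config and a
# feature cache shared by every protocol run on this seed (same frozen
# backbone, same stores). Memoized per (seed, casts) for the test run.
scenario_bundle <- function(seed, stain_casts = TRUE) {
  key <- paste0("scen_", seed, "_", stain_casts)
  if (is.null(.fixture_cache[[key]])) {
    sc <- make_multicenter_scenario(seed = seed, stain_casts = stain_casts)
    dirs <- file.path(tempdir(), paste0("wsimil_scen_", seed, "_", stain_casts,
                                        "_", names(sc)))
    tiled <- Map(function(co, d) tile_cohort(co, d, seed = seed), sc, dirs)
    .fixture_cache[[key]] <- list(
      tiled = tiled,
      config = desk_config(seed),
      cache = new.env(parent = emptyenv())
    )
  }
  .fixture_cache[[key]]
}

# A store of n synthetic high-contrast tiles for MIL-level tests, built
# directly from one slide of the small cohort.
small_store <- function(seed = 11L, slide = 1L) {
  co <- small_tiled_cohort(seed)
  read_tile_store(co$manifest$store_path[slide])
}

# Random RGB image array.
random_rgb <- function(H, W, seed) {
  wsimil:::with_seed(seed, array(sample(0:255, H * W * 3L, replace = TRUE),
                                 dim = c(H, W, 3L)))
}
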